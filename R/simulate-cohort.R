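#' Configuration for the synthetic cohort generator
#'
#' Bundles the generative parameters for a matched Ribo-seq/RNA-seq cohort in
#' which designated RBP genes causally shift the mRNA abundance and/or the
#' translational efficiency (TE) of planted target genes. Effects act on the
#' log scale and are additive across RBPs, so overlapping regulation composes
#' cleanly and counts stay positive.
#'
#' @param n_genes Number of genes (includes the RBP genes).
#' @param n_samples Cohort size (number of paired libraries); default 80,
#'   the size of a typical large translatome cohort.
#' @param rbps Tibble describing the RBPs, one row each, with columns
#'   `rbp_id` (optional; defaults to the first genes), `trait`
#'   (`"mRNA"`, `"TE"`, `"both"` or `"null"`), `n_targets`, `effect_size`
#'   (slope on the standardized RBP log-expression) and `effect_sign`
#'   (+1/-1, or 0 to randomize per target). For `"both"`, `n_targets` genes
#'   are planted per trait with `overlap` fraction shared.
#' @param overlap Fraction of shared targets between the mRNA and TE target
#'   sets of dual-trait RBPs (default 0: disjoint sets, reproducing the
#'   low-overlap regime).
#' @param dispersion Negative-binomial dispersion (1/size); must be > 0.
#' @param library_size_range Pair of relative library-depth bounds; per-library
#'   true size factors are drawn uniformly between them.
#' @param clip_fp_rate,clip_fn_rate False-positive / false-negative rates for
#'   the CLIP peak generator (stored here so one config describes a study).
#' @param baseline_meanlog,baseline_sdlog Natural-log mean/sd of baseline mRNA
#'   expression per gene.
#' @param seed Integer seed for all generator stages.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes,
                       n_samples = 80L,
                       rbps,
                       overlap = 0,
                       dispersion = 0.1,
                       library_size_range = c(0.7, 1.4),
                       clip_fp_rate = 0.05,
                       clip_fn_rate = 0.05,
                       baseline_meanlog = log(200),
                       baseline_sdlog = 1,
                       seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  dispersion <- check_positive(dispersion, "dispersion")
  check_fraction(overlap, "overlap")
  check_fraction(clip_fp_rate, "clip_fp_rate")
  check_fraction(clip_fn_rate, "clip_fn_rate")
  rbps <- tibble::as_tibble(rbps)
  if (!all(c("trait", "n_targets", "effect_size") %in% names(rbps))) {
    stop_config("`rbps` needs columns trait, n_targets, effect_size")
  }
  if (!all(rbps$trait %in% c("mRNA", "TE", "both", "null"))) {
    stop_config("rbps$trait must be one of mRNA, TE, both, null")
  }
  if (any(rbps$n_targets > n_genes)) {
    stop_config("n_targets cannot exceed n_genes")
  }
  if (!"effect_sign" %in% names(rbps)) rbps$effect_sign <- 1
  if (!"rbp_id" %in% names(rbps)) {
    rbps$rbp_id <- sprintf("G%05d", seq_len(nrow(rbps)))
  }
  structure(
    list(n_genes = n_genes, n_samples = n_samples, rbps = rbps,
         overlap = overlap, dispersion = dispersion,
         library_size_range = as.numeric(library_size_range),
         clip_fp_rate = clip_fp_rate, clip_fn_rate = clip_fn_rate,
         baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a matched Ribo-seq / RNA-seq cohort with planted RBP effects
#'
#' The generative model: each RBP's log-expression varies across samples as a
#' standard-normal latent `z`; a planted target's log mean mRNA abundance
#' gains `effect_size * z` (mRNA targets) and its log TE gains
#' `effect_size * z` (TE targets). RNA counts are negative-binomial around
#' `sizefactor * mu_mRNA`, Ribo counts around `sizefactor * mu_mRNA * TE`,
#' sharing one dispersion. Effects from multiple RBPs add on the log scale.
#'
#' @param config A [sim_config()].
#' @param annotation Annotation tibble; its genes define the gene universe
#'   (must contain at least `config$n_genes` genes).
#' @param truth,clip_targets Optional planted regulatory map (and CLIP-bound
#'   sets) from a previous [simulate_cohort()] call: supply both to simulate
#'   an independent cohort (e.g. a replication cohort) sharing the same
#'   ground truth.
#' @return A list of class `sim_cohort`: `rna` and `ribo` count matrices
#'   (genes x samples, shared dimnames), `truth` tibble (one row per planted
#'   (rbp, trait, gene) effect), `clip_targets` (the CLIP-bound gene set per
#'   RBP — planted targets, plus effect-free bound genes for null RBPs),
#'   `rbp_ids`, `size_factors` (true per-library factors, RNA then Ribo),
#'   and the `config`.
#' @export
#' @examples
#' ann <- simulate_annotation(60, seed = 1)
#' cfg <- sim_config(60, n_samples = 20,
#'                   rbps = tibble::tibble(trait = "TE", n_targets = 10,
#'                                         effect_size = 1),
#'                   seed = 1)
#' co <- simulate_cohort(cfg, ann)
#' dim(co$rna)
simulate_cohort <- function(config, annotation, truth = NULL,
                            clip_targets = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- unique(annotation$gene_id)
  if (length(genes) < config$n_genes) {
    stop_config("annotation has fewer genes than config$n_genes")
  }
  genes <- genes[seq_len(config$n_genes)]
  rbps <- config$rbps
  if (!all(rbps$rbp_id %in% genes)) {
    stop_config("all rbp_id values must be gene ids in the annotation")
  }
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))

  with_seed(child_seed(config$seed, "cohort"), {
    # latent standardized RBP expression, one row per RBP
    z <- matrix(rnorm(nrow(rbps) * n), nrow = nrow(rbps),
                dimnames = list(rbps$rbp_id, samples))

    # planted regulatory map (reused verbatim when supplied)
    plant <- is.null(truth)
    non_rbp <- setdiff(genes, rbps$rbp_id)
    if (plant) {
    truth <- vector("list", nrow(rbps))
    for (i in seq_len(nrow(rbps))) {
      r <- rbps[i, ]
      traits <- switch(r$trait, mRNA = "mRNA", TE = "TE",
                       both = c("mRNA", "TE"), null = character(0))
      if (length(traits) == 0L) {
        truth[[i]] <- tibble(rbp_id = r$rbp_id, trait = character(0),
                             gene_id = character(0), effect_size = numeric(0),
                             effect_sign = numeric(0))
        next
      }
      k <- r$n_targets
      if (length(traits) == 2L) {
        n_shared <- round(config$overlap * k)
        if (2L * k - n_shared > length(non_rbp)) {
          stop_config("not enough non-RBP genes for the dual target sets")
        }
        pool <- sample(non_rbp, 2L * k - n_shared)
        shared <- if (n_shared > 0) pool[seq_len(n_shared)] else character(0)
        rest <- setdiff(pool, shared)
        sets <- list(mRNA = c(shared, rest[seq_len(k - n_shared)]),
                     TE = c(shared, rest[(k - n_shared) + seq_len(k - n_shared)]))
      } else {
        sets <- setNames(list(sample(non_rbp, k)), traits)
      }
      truth[[i]] <- purrr::imap(sets, function(gs, tr) {
        sgn <- if (r$effect_sign == 0) sample(c(-1, 1), length(gs), TRUE)
               else rep(r$effect_sign, length(gs))
        tibble(rbp_id = r$rbp_id, trait = tr, gene_id = gs,
               effect_size = r$effect_size, effect_sign = sgn)
      }) |> bind_rows()
    }
    truth <- bind_rows(truth)

    # CLIP-bound gene sets: planted targets, plus (for null RBPs) bound
    # genes with no expression effect
    clip_targets <- truth |> distinct(.data$rbp_id, .data$gene_id)
    for (i in which(rbps$trait == "null")) {
      clip_targets <- bind_rows(
        clip_targets,
        tibble(rbp_id = rbps$rbp_id[i],
               gene_id = sample(non_rbp, rbps$n_targets[i]))
      )
    }
    } # end planting
    if (is.null(clip_targets)) {
      clip_targets <- truth |> distinct(.data$rbp_id, .data$gene_id)
    }

    # baseline expression and TE
    base_mu <- exp(rnorm(length(genes), config$baseline_meanlog,
                         config$baseline_sdlog))
    names(base_mu) <- genes
    base_te <- exp(rnorm(length(genes), 0, 0.25))
    names(base_te) <- genes

    log_mu <- matrix(log(base_mu), nrow = length(genes), ncol = n,
                     dimnames = list(genes, samples))
    log_te <- matrix(log(base_te), nrow = length(genes), ncol = n,
                     dimnames = list(genes, samples))

    # RBP expression is its own mRNA row: one log-sd unit per z unit
    for (i in seq_len(nrow(rbps))) {
      log_mu[rbps$rbp_id[i], ] <- log_mu[rbps$rbp_id[i], ] + 0.5 * z[i, ]
    }
    # planted effects, additive on log scale
    if (nrow(truth) > 0) {
      for (j in seq_len(nrow(truth))) {
        tgt <- truth$gene_id[j]
        zi <- z[truth$rbp_id[j], ]
        eff <- truth$effect_size[j] * truth$effect_sign[j] * zi
        if (truth$trait[j] == "mRNA") {
          log_mu[tgt, ] <- log_mu[tgt, ] + eff
        } else {
          log_te[tgt, ] <- log_te[tgt, ] + eff
        }
      }
    }

    sf <- runif(2L * n, config$library_size_range[1],
                config$library_size_range[2])
    sf_rna <- sf[seq_len(n)]
    sf_ribo <- sf[n + seq_len(n)]
    size <- 1 / config$dispersion

    mu_rna <- exp(log_mu) * rep(sf_rna, each = length(genes))
    mu_ribo <- exp(log_mu + log_te) * rep(sf_ribo, each = length(genes))
    rna <- matrix(rnbinom(length(mu_rna), mu = mu_rna, size = size),
                  nrow = length(genes), dimnames = dimnames(log_mu))
    ribo <- matrix(rnbinom(length(mu_ribo), mu = mu_ribo, size = size),
                   nrow = length(genes), dimnames = dimnames(log_mu))

    structure(
      list(rna = rna, ribo = ribo, truth = truth,
           clip_targets = clip_targets, rbp_ids = rbps$rbp_id,
           size_factors = tibble(
             library_id = c(paste0(samples, "_rna"), paste0(samples, "_ribo")),
             sample_id = rep(samples, 2), assay = rep(c("RNA", "RIBO"), each = n),
             true_sf = c(sf_rna, sf_ribo)),
           config = config),
      class = "sim_cohort"
    )
  })
}
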