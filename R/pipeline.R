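#' Analysis thresholds for a cohort study
#'
#' One declarative bundle of every tunable threshold the pipeline consumes.
#' Unknown keys are rejected; values are range-checked.
#'
#' @param alpha Significance level for BH-adjusted correlations, enrichment
#'   classification and replication (default 0.05).
#' @param min_mean_fpkm,min_samples Expression-filter bounds (defaults 1, 20).
#' @param idr_max,peak_p_max,fc_min CLIP peak filter (defaults 0.01, 1e-5, 8).
#' @param n_null_sets Sampled null sets per enrichment test (default 100000).
#' @param n_perm Replication permutations (default 10000).
#' @param min_pairs Minimum complete pairs per correlation (default 10).
#' @param min_utr_len Minimum 5'UTR length for MFE comparisons (default 20).
#' @param subsample_n Genes per group in length-matched subsampling
#'   (default 50).
#' @return Named list of class `study_thresholds`.
#' @export
study_thresholds <- function(alpha = 0.05, min_mean_fpkm = 1,
                             min_samples = 20L, idr_max = 0.01,
                             peak_p_max = 1e-5, fc_min = 8,
                             n_null_sets = 1e5, n_perm = 1e4,
                             min_pairs = 10L, min_utr_len = 20L,
                             subsample_n = 50L) {
  th <- list(alpha = check_fraction(alpha, "alpha"),
             min_mean_fpkm = check_positive(min_mean_fpkm, "min_mean_fpkm"),
             min_samples = check_count(min_samples, "min_samples", min = 0L),
             idr_max = check_fraction(idr_max, "idr_max"),
             peak_p_max = check_fraction(peak_p_max, "peak_p_max"),
             fc_min = check_positive(fc_min, "fc_min"),
             n_null_sets = check_count(n_null_sets, "n_null_sets"),
             n_perm = check_count(n_perm, "n_perm"),
             min_pairs = check_count(min_pairs, "min_pairs"),
             min_utr_len = check_count(min_utr_len, "min_utr_len"),
             subsample_n = check_count(subsample_n, "subsample_n"))
  structure(th, class = "study_thresholds")
}

#' Write a complete synthetic study to disk
#'
#' Generates annotation, cohort count matrices, replicated CLIP peaks, 5'UTR
#' sequences, junction counts and the planted truth, and writes every input
#' [run_study()] needs (all files round-trip through the package's own
#' readers). Optionally simulates an independent replication cohort sharing
#' the same truth and writes its correlation table.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param replication Simulate a 20-sample replication cohort and write its
#'   RBP-target correlation table (default TRUE).
#' @return Invisibly, a named list of file paths plus the in-memory bundle.
#' @export
simulate_study <- function(config, dir, replication = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(config$n_genes,
                             seed = child_seed(config$seed, "annotation"))
  cohort <- simulate_cohort(config, ann)
  peaks <- simulate_clip_peaks(cohort$clip_targets, ann,
                               fp_rate = config$clip_fp_rate,
                               fn_rate = config$clip_fn_rate,
                               seed = child_seed(config$seed, "clip"))

  # structured 5'UTRs for positively correlated TE targets, unstructured
  # elsewhere: the structural contrast the MFE comparison should recover
  te_pos <- unique(cohort$truth$gene_id[cohort$truth$trait == "TE" &
                                          cohort$truth$effect_sign > 0])
  genes <- unique(ann$gene_id)
  class_map <- setNames(ifelse(genes %in% te_pos, "structured",
                               "unstructured"), genes)
  utrs <- simulate_utr_sequences(ann, class_map,
                                 seed = child_seed(config$seed, "utr"))

  # splicing driven by the first TE-coupled RBP, when present
  te_rbps <- config$rbps$rbp_id[config$rbps$trait %in% c("TE", "both")]
  junctions <- NULL
  if (length(te_rbps) > 0) {
    z <- log1p(cohort$ribo[te_rbps[1], ])
    junctions <- simulate_splicing(cohort$truth, ann, te_rbps[1], z,
                                   coupling = 0.8,
                                   seed = child_seed(config$seed, "splice"))
  }

  paths <- list(
    annotation = file.path(dir, "annotation.gtf"),
    rna = file.path(dir, "rna_counts.tsv"),
    ribo = file.path(dir, "ribo_counts.tsv"),
    peaks = file.path(dir, "peaks.bed"),
    utr_fasta = file.path(dir, "utr5.fasta"),
    truth = file.path(dir, "truth.tsv"),
    rbps = file.path(dir, "rbps.tsv")
  )
  write_annotation(ann, paths$annotation)
  write_counts_tsv(cohort$rna, paths$rna)
  write_counts_tsv(cohort$ribo, paths$ribo)
  write_peaks_bed(peaks, paths$peaks)
  write_utr_fasta(utrs, paths$utr_fasta)
  write_table_tsv(cohort$truth, paths$truth)
  write_table_tsv(config$rbps |> select("rbp_id", "trait"), paths$rbps)
  if (!is.null(junctions)) {
    paths$junctions <- file.path(dir, "junctions.tsv")
    write_table_tsv(junctions, paths$junctions)
  }

  if (replication) {
    repl_cfg <- config
    repl_cfg$n_samples <- 20L
    repl_cfg$seed <- child_seed(config$seed, "replication")
    class(repl_cfg) <- "sim_config"
    repl <- simulate_cohort(repl_cfg, ann, truth = cohort$truth,
                            clip_targets = cohort$clip_targets)
    repl_tbl <- replication_correlation_table(repl, cohort$clip_targets)
    paths$replication <- file.path(dir, "replication_correlations.tsv")
    write_table_tsv(repl_tbl, paths$replication)
  }
  invisible(c(paths, list(annotation_tbl = ann, cohort = cohort,
                          peaks_tbl = peaks, utrs = utrs,
                          junctions_tbl = junctions)))
}

# Correlation table (rho per CLIP rbp-gene pair, both traits) for a
# replication cohort, via the package's own quantification + correlation path.
replication_correlation_table <- function(cohort, clip_targets) {
  q <- quantify_cohort(cohort$rna, cohort$ribo, min_samples = 0L)
  pairs <- clip_targets |>
    distinct(.data$rbp_id, .data$gene_id) |>
    tidyr::crossing(trait = c("mRNA", "TE"))
  pairs |>
    group_by(.data$rbp_id, .data$trait) |>
    group_split() |>
    purrr::map(function(d) {
      rbp <- d$rbp_id[1]
      if (!rbp %in% rownames(q$ribo_norm)) return(NULL)
      tm <- if (d$trait[1] == "mRNA") q$rna_norm else q$te
      gs <- intersect(d$gene_id, rownames(tm))
      if (length(gs) == 0L) return(NULL)
      res <- spearman_vs_matrix(q$ribo_norm[rbp, ], tm[gs, , drop = FALSE],
                                min_pairs = 10L)
      tibble(rbp_id = rbp, gene_id = res$gene_id, trait = d$trait[1],
             rho = res$rho)
    }) |>
    bind_rows()
}

# Shared quantification stage: joint size factors, normalization, TE.
quantify_cohort <- function(rna, ribo, cds_lengths = NULL,
                            min_mean_fpkm = 1, min_samples = 20L) {
  joint <- cbind(rna, ribo)
  colnames(joint) <- c(paste0(colnames(rna), "_rna"),
                       paste0(colnames(ribo), "_ribo"))
  sf <- estimate_size_factors(joint)
  n <- ncol(rna)
  rna_norm <- normalize_counts(rna, unname(sf[seq_len(n)]))
  ribo_norm <- normalize_counts(ribo, unname(sf[n + seq_len(n)]))
  keep <- rownames(rna)
  if (!is.null(cds_lengths) && min_samples > 0L) {
    fpkm <- compute_fpkm(rna, cds_lengths[rownames(rna)])
    keep <- filter_expressed(fpkm, rna, ribo, min_mean_fpkm, min_samples)
  }
  list(
    size_factors = sf,
    rna_norm = rna_norm[keep, , drop = FALSE],
    ribo_norm = ribo_norm[keep, , drop = FALSE],
    te = compute_te(ribo_norm[keep, , drop = FALSE],
                    rna_norm[keep, , drop = FALSE]),
    genes = keep
  )
}

#' Default synthetic fixture configuration
#'
#' The packaged benchmark study: an 80-sample cohort of 600 genes with eight
#' RBPs, two per regulatory class (mRNA-only, TE-only, dual-trait with
#' disjoint target sets, null), 40 CLIP targets each, unit effect size with
#' per-target random sign, and negative-binomial dispersion 0.1 — a
#' desk-scale analogue of a large translatome cohort.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
default_fixture_config <- function(seed = 1L) {
  sim_config(
    n_genes = 600L, n_samples = 80L,
    rbps = tibble(
      rbp_id = sprintf("G%05d", 1:8),
      trait = rep(c("mRNA", "TE", "both", "null"), each = 2L),
      n_targets = 40L, effect_size = 1, effect_sign = 0
    ),
    overlap = 0, dispersion = 0.1, seed = seed
  )
}

#' Run the full RBP-trait analysis on a study directory
#'
#' Executes the pipeline end to end: joint normalization and expression
#' filtering, CLIP peak scoring / IDR / filtering / pooling / target
#' assignment, per-RBP trait correlations, the empirical set-sampling
#' enrichment test with Glass' delta, RBP classification and target-set
#' overlap, correlation-profile clustering, 5'UTR MFE comparisons, and (when
#' a replication table is present) directional replication. Stage outputs
#' are written under `out_dir` with a manifest; the returned summary has one
#' row per RBP.
#'
#' @param dir Study directory from [simulate_study()] (or containing the
#'   equivalent files).
#' @param out_dir Output directory (default `file.path(dir, "results")`).
#' @param thresholds A [study_thresholds()].
#' @param seed Integer seed for the enrichment sampling.
#' @return List of class `rbp_study`: `summary` (per-RBP tibble),
#'   `classification`, `enrichment` records, correlation `records`,
#'   `targets`, `overlap`, `mfe`, `replication`, `clustering`, `genes`
#'   (filtered universe) and `paths`.
#' @export
run_study <- function(dir, out_dir = file.path(dir, "results"),
                      thresholds = study_thresholds(), seed = 1L) {
  stopifnot(inherits(thresholds, "study_thresholds"))
  need <- c("annotation.gtf", "rna_counts.tsv", "ribo_counts.tsv", "peaks.bed")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    stop_config(paste0("missing study input(s): ",
                       paste(missing, collapse = ", ")))
  }
  ann <- read_annotation(file.path(dir, "annotation.gtf"))
  rna <- read_counts_tsv(file.path(dir, "rna_counts.tsv"))
  ribo <- read_counts_tsv(file.path(dir, "ribo_counts.tsv"))
  if (thresholds$min_samples > ncol(rna)) {
    stop_config("min_samples exceeds the cohort size")
  }
  peaks <- read_peaks_bed(file.path(dir, "peaks.bed"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("targets", "correlations", "enrichment", "features",
                "replication")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  }

  # -- quantification ---------------------------------------------------
  cds_len <- feature_lengths(ann) |>
    group_by(.data$gene_id) |> slice(1L) |> ungroup()
  cds_lengths <- setNames(cds_len$cds_len, cds_len$gene_id)
  q <- quantify_cohort(rna, ribo, cds_lengths,
                       thresholds$min_mean_fpkm, thresholds$min_samples)

  # -- CLIP targets ------------------------------------------------------
  tg <- derive_targets(peaks, ann, idr_max = thresholds$idr_max,
                       p_max = thresholds$peak_p_max,
                       fc_min = thresholds$fc_min)
  write_table_tsv(tg$targets, file.path(out_dir, "targets", "targets.tsv"))
  target_sets <- split(tg$targets$gene_id, tg$targets$rbp_id)

  # -- correlations + enrichment ----------------------------------------
  rbp_ids <- intersect(names(target_sets), q$genes)
  records <- list(); enr_records <- list(); enr_objects <- list()
  for (rbp in rbp_ids) {
    x <- q$ribo_norm[rbp, ]
    for (tr in c("mRNA", "TE")) {
      tm <- if (tr == "mRNA") q$rna_norm else q$te
      tset <- intersect(target_sets[[rbp]], q$genes)
      if (length(tset) == 0L) next
      e <- enrichment_test(
        x, tm, tset, universe = q$genes, rbp_id = rbp, trait = tr,
        n_sets = thresholds$n_null_sets, alpha = thresholds$alpha,
        seed = child_seed(seed, paste0(rbp, tr)),
        min_pairs = thresholds$min_pairs
      )
      records[[paste(rbp, tr)]] <- e$records
      enr_records[[paste(rbp, tr)]] <- e$record
      enr_objects[[paste(rbp, tr)]] <- e
    }
  }
  records <- bind_rows(records)
  enr_records <- bind_rows(enr_records)
  write_table_tsv(records, file.path(out_dir, "correlations", "records.tsv"))
  write_table_tsv(enr_records, file.path(out_dir, "enrichment", "records.tsv"))

  classification <- classify_rbps(enr_records, alpha = thresholds$alpha)
  write_table_tsv(classification,
                  file.path(out_dir, "enrichment", "classification.tsv"))

  # -- overlap of significant target sets per RBP -----------------------
  sig_sets <- function(rbp, tr) {
    records |>
      filter(.data$rbp_id == rbp, .data$trait == tr, .data$significant) |>
      pull(.data$gene_id)
  }
  overlap <- purrr::map(classification$rbp_id, function(rbp) {
    target_overlap(sig_sets(rbp, "mRNA"), sig_sets(rbp, "TE")) |>
      mutate(rbp_id = rbp)
  }) |> bind_rows()
  write_table_tsv(overlap, file.path(out_dir, "enrichment", "overlap.tsv"))

  # -- features ----------------------------------------------------------
  clustering <- NULL
  if (length(rbp_ids) >= 2L && nrow(records) > 0) {
    rho_wide <- records |>
      filter(.data$trait == "TE") |>
      select("rbp_id", "gene_id", "rho") |>
      pivot_wider(names_from = "gene_id", values_from = "rho")
    if (nrow(rho_wide) >= 2L) {
      m <- as.matrix(rho_wide[-1])
      rownames(m) <- rho_wide$rbp_id
      clustering <- cluster_correlations(m)
      write_table_tsv(tidy(clustering),
                      file.path(out_dir, "features", "te_cluster_merges.tsv"))
    }
  }
  mfe_tbl <- NULL
  utr_path <- file.path(dir, "utr5.fasta")
  if (file.exists(utr_path) && nrow(records) > 0) {
    utrs <- read_utr_fasta(utr_path)
    need <- unique(records$gene_id[records$trait == "TE" &
                                     records$significant])
    need <- intersect(need, names(utrs))
    nmfe <- setNames(normalized_mfe(utrs[need],
                                    min_length = thresholds$min_utr_len),
                     need)
    mfe_tbl <- records |>
      filter(.data$trait == "TE") |>
      group_by(.data$rbp_id) |>
      group_split() |>
      purrr::map(function(d) {
        compare_mfe_by_sign(d, nmfe = nmfe) |>
          mutate(rbp_id = d$rbp_id[1])
      }) |>
      bind_rows()
    if (nrow(mfe_tbl) > 0) {
      mfe_tbl$p_adj <- adjust_bh(mfe_tbl$p)
      write_table_tsv(mfe_tbl, file.path(out_dir, "features", "utr_mfe.tsv"))
    }
  }

  # -- replication -------------------------------------------------------
  repl_tbl <- NULL
  repl_path <- file.path(dir, "replication_correlations.tsv")
  if (file.exists(repl_path) && nrow(records) > 0) {
    repl <- read_table_tsv(repl_path)
    repl_tbl <- replicate_correlations(records, repl,
                                       n_perm = thresholds$n_perm,
                                       seed = child_seed(seed, "replication"))
    write_table_tsv(repl_tbl,
                    file.path(out_dir, "replication", "replication.tsv"))
  }

  # -- summary -----------------------------------------------------------
  delta_wide <- enr_records |>
    select("rbp_id", "trait", "glass_delta", "emp_p") |>
    pivot_wider(names_from = "trait",
                values_from = c("glass_delta", "emp_p"))
  summary <- classification |>
    left_join(delta_wide, by = "rbp_id") |>
    left_join(overlap |> select("rbp_id", "overlap_pct"), by = "rbp_id")
  write_table_tsv(summary, file.path(out_dir, "summary.tsv"))

  manifest <- c(
    sprintf("run_seed: %d", seed),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("rbptraits"))),
    sprintf("n_genes_filtered: %d", length(q$genes)),
    sprintf("n_rbps_analyzed: %d", length(rbp_ids)),
    vapply(names(thresholds), function(k)
      sprintf("threshold %s: %s", k, format(thresholds[[k]])), character(1))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  structure(
    list(summary = summary, classification = classification,
         enrichment = enr_records, records = records, targets = tg$targets,
         overlap = overlap, mfe = mfe_tbl, replication = repl_tbl,
         clustering = clustering, genes = q$genes,
         enrichment_objects = enr_objects,
         paths = list(dir = dir, out_dir = out_dir)),
    class = "rbp_study"
  )
}

#' @export
print.rbp_study <- function(x, ...) {
  cat(sprintf("RBP trait study: %d RBPs over %d filtered genes\n",
              nrow(x$summary), length(x$genes)))
  print(table(x$classification$label))
  invisible(x)
}

#' Score label recovery against the planted truth
#'
#' Compares each RBP's assigned label with its planted role and summarizes
#' accuracy, per-class confusion, and the mean significant-target overlap of
#' planted dual-trait RBPs.
#'
#' @param study An `rbp_study` from [run_study()] (or its `summary` tibble).
#' @param truth_rbps Tibble with `rbp_id` and planted `trait` (`mRNA`, `TE`,
#'   `both`, `null`), e.g. the `rbps.tsv` written by [simulate_study()].
#' @return List with `accuracy`, the joined per-RBP `table`, and
#'   `dual_overlap_pct` (mean over planted dual RBPs; `NA` when none).
#' @export
score_recovery <- function(study, truth_rbps) {
  summary <- if (inherits(study, "rbp_study")) study$summary else study
  expected <- c(mRNA = "mRNA-RBP", TE = "TE-RBP", both = "multifunctional",
                null = "none")
  tbl <- truth_rbps |>
    mutate(expected = expected[.data$trait]) |>
    left_join(summary, by = "rbp_id") |>
    mutate(assigned = dplyr::coalesce(.data$label, "none"),
           correct = .data$assigned == .data$expected)
  dual <- tbl |> filter(.data$trait == "both")
  list(
    accuracy = mean(tbl$correct),
    table = tbl |> select("rbp_id", "trait", "expected", "assigned",
                          "correct", dplyr::any_of("overlap_pct")),
    dual_overlap_pct = if (nrow(dual) > 0)
      mean(dual$overlap_pct, na.rm = TRUE) else NA_real_
  )
}
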