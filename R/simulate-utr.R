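#' Simulate 5'UTR sequences with controlled structural complexity
#'
#' Builds RNA sequences matching each transcript's annotated 5'UTR length.
#' Genes labelled `"structured"` receive GC-rich palindromic stem-loops
#' (high self-complementarity, strongly negative minimum free energy);
#' `"unstructured"` genes are built from A/C-biased background in which no
#' Watson-Crick or wobble pair is possible for most positions, so their MFE
#' sits near zero.
#'
#' @param annotation Annotation tibble (5'UTR lengths are taken from it; for
#'   multi-isoform genes the first transcript is used).
#' @param class_map Named character vector or tibble (`gene_id`, `class`)
#'   assigning `"structured"` or `"unstructured"` per gene; genes absent from
#'   the map are skipped.
#' @param seed Integer seed; identical seeds give identical sequences.
#'
#' @return A named character vector of RNA sequences (A/C/G/U), one per gene.
#' @export
simulate_utr_sequences <- function(annotation, class_map, seed = NULL) {
  if (is.data.frame(class_map)) {
    class_map <- setNames(class_map$class, class_map$gene_id)
  }
  bad <- setdiff(unique(class_map), c("structured", "unstructured"))
  if (length(bad) > 0) {
    stop_config(paste0("unknown UTR class label(s): ",
                       paste(bad, collapse = ", ")))
  }
  lens <- feature_lengths(annotation) |>
    group_by(.data$gene_id) |>
    slice(1L) |>
    ungroup()
  lens <- lens[lens$gene_id %in% names(class_map), ]

  with_seed(seed, {
    seqs <- vapply(seq_len(nrow(lens)), function(i) {
      L <- lens$utr5_len[i]
      cls <- class_map[[lens$gene_id[i]]]
      if (cls == "unstructured") {
        paste(sample(c("A", "C"), L, TRUE, prob = c(0.7, 0.3)), collapse = "")
      } else {
        structured_utr(L)
      }
    }, character(1))
    setNames(seqs, lens$gene_id)
  })
}

# GC palindromic stems over A/C background: arm + AAAA loop + reverse
# complement arm, tiled until the annotated length is filled.
structured_utr <- function(L) {
  out <- character(0)
  used <- 0L
  while (used < L) {
    arm_len <- sample(6:10, 1L)
    need <- 2L * arm_len + 4L
    if (used + need > L) {
      out <- c(out, sample(c("A", "C"), L - used, TRUE))
      used <- L
    } else {
      arm <- sample(c("G", "C"), arm_len, TRUE, prob = c(0.6, 0.4))
      rc <- rev(chartr_vec(arm))
      spacer_len <- min(L - used - need, sample(3:8, 1L))
      spacer <- sample(c("A", "C"), spacer_len, TRUE)
      out <- c(out, arm, rep("A", 4L), rc, spacer)
      used <- used + need + spacer_len
    }
  }
  paste(out[seq_len(L)], collapse = "")
}

chartr_vec <- function(x) c(A = "U", C = "G", G = "C", U = "A")[x]

#' Write / read 5'UTR FASTA
#'
#' Thin wrappers over Biostrings for the package's FASTA interchange.
#' @param seqs Named character vector of RNA sequences.
#' @param path File path.
#' @return `read_utr_fasta()` returns a named character vector (T converted
#'   to U); `write_utr_fasta()` returns `path` invisibly.
#' @export
write_utr_fasta <- function(seqs, path) {
  ss <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_utr_fasta
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- chartr("Tt", "Uu", toupper(as.character(ss)))
  setNames(out, names(ss))
}
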