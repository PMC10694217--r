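# Classification of paralog-group-specific alignment columns and their
# conservation in reconstructed ancestral sequences.

# fixed conservative-substitution classes used when a group is conserved as
# a small set of biochemically similar residues (e.g. Val/Ile at a site
# where VL has Thr)
SIMILARITY_CLASSES <- list(
  aliphatic = c("I", "L", "V", "M"),
  aromatic  = c("F", "Y", "W"),
  hydroxyl  = c("S", "T"),
  acidic    = c("D", "E"),
  basic     = c("K", "R"),
  amide     = c("N", "Q"))

#' Specificity rule parameters
#'
#' The operational definition of "conserved in the FRL sequences but not the
#' VL sequences". A column is called `GROUP_SPECIFIC` when (i) the gap
#' fraction is at most `max_gap_fraction` in both groups, (ii) after
#' dropping residues at within-group frequency at or below `max_noise_freq`
#' the FRL residue set is non-empty and disjoint from the VL set, and (iii)
#' the FRL set is a single residue at frequency at least
#' `min_frl_dominance`, or (if `allow_similarity_class`) a subset of one
#' similarity class (`ILVM`, `FYW`, `ST`, `DE`, `KR`, `NQ`) with total
#' frequency at least `min_frl_dominance`.
#'
#' Frequencies use raw sequence counts over non-gap, non-`X` residues, so
#' duplicated sequences weigh in proportion to their copy number.
#'
#' @param min_frl_dominance Minimum frequency of the conserved FRL residue
#'   (or class) within the FRL group. Default 0.90.
#' @param max_noise_freq Residues at or below this within-group frequency
#'   are ignored as noise. Default 0.05.
#' @param max_gap_fraction Maximum per-group gap fraction before a column is
#'   called `GAP_DOMINATED`. Default 0.50.
#' @param allow_similarity_class Allow a conserved similarity class instead
#'   of a single residue. Default `TRUE`.
#' @return An object of class `specificity_rule`.
#' @export
specificity_rule <- function(min_frl_dominance = 0.90,
                             max_noise_freq = 0.05,
                             max_gap_fraction = 0.50,
                             allow_similarity_class = TRUE) {
  for (v in c(min_frl_dominance, max_noise_freq, max_gap_fraction))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("rule fractions must lie in [0, 1]")
  structure(list(min_frl_dominance = min_frl_dominance,
                 max_noise_freq = max_noise_freq,
                 max_gap_fraction = max_gap_fraction,
                 allow_similarity_class = isTRUE(allow_similarity_class)),
            class = "specificity_rule")
}

# residue frequency table of one group at one column
.column_freqs <- function(chars) {
  res <- chars[chars != "-" & chars != "X"]
  if (length(res) == 0L) return(numeric(0))
  tab <- table(res)
  setNames(as.numeric(tab) / length(res), names(tab))
}

# the similarity class (name) containing all residues in `set`, or NA
.covering_class <- function(set) {
  for (nm in names(SIMILARITY_CLASSES))
    if (all(set %in% SIMILARITY_CLASSES[[nm]])) return(nm)
  NA_character_
}

#' Classify alignment columns as FRL-specific
#'
#' Applies a [specificity_rule()] to every column of a grouped alignment.
#' Sequences labelled `OUTGROUP` are ignored. Statuses are
#' `GROUP_SPECIFIC`, `SHARED_CONSERVED` (one residue dominates both
#' groups), `VARIABLE`, or `GAP_DOMINATED`.
#'
#' @param aln A [grouped_alignment()] with at least one FRL and one VL
#'   sequence.
#' @param rule A [specificity_rule()].
#' @return Data frame of class `column_classification`, one row per column:
#'   `column`, `status`, `frl_set` and `vl_set` (comma-separated
#'   noise-filtered residue sets), `frl_consensus`, `frl_gap_fraction`,
#'   `vl_gap_fraction`, `ancestral_state` (NA until scored) and
#'   `ancestral_conserved`.
#' @seealso [score_ancestral_conservation()]
#' @export
classify_columns <- function(aln, rule = specificity_rule()) {
  stopifnot(inherits(aln, "grouped_alignment"),
            inherits(rule, "specificity_rule"))
  frl_ids <- names(aln$seq)[aln$group == "FRL"]
  vl_ids <- names(aln$seq)[aln$group == "VL"]
  if (length(frl_ids) == 0L || length(vl_ids) == 0L)
    stop("classification requires at least one FRL and one VL sequence")
  mat <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(mat) <- names(aln$seq)
  frl <- mat[frl_ids, , drop = FALSE]
  vl <- mat[vl_ids, , drop = FALSE]

  n <- aln$n_columns
  status <- character(n)
  frl_set <- vl_set <- character(n)
  frl_cons <- rep(NA_character_, n)
  fgap <- vgap <- numeric(n)
  for (j in seq_len(n)) {
    fc <- frl[, j]; vc <- vl[, j]
    fgap[j] <- mean(fc == "-"); vgap[j] <- mean(vc == "-")
    ff <- .column_freqs(fc); vf <- .column_freqs(vc)
    if (length(ff)) {
      top <- max(ff)
      frl_cons[j] <- sort(names(ff)[ff == top])[1L]
    }
    f_keep <- ff[ff > rule$max_noise_freq]
    v_keep <- vf[vf > rule$max_noise_freq]
    frl_set[j] <- paste(sort(names(f_keep)), collapse = ",")
    vl_set[j] <- paste(sort(names(v_keep)), collapse = ",")
    if (fgap[j] > rule$max_gap_fraction || vgap[j] > rule$max_gap_fraction) {
      status[j] <- "GAP_DOMINATED"
      next
    }
    disjoint <- length(f_keep) > 0L &&
      !any(names(f_keep) %in% names(v_keep))
    if (disjoint) {
      dominant <-
        (length(f_keep) == 1L && f_keep[[1L]] >= rule$min_frl_dominance) ||
        (rule$allow_similarity_class &&
           !is.na(.covering_class(names(f_keep))) &&
           sum(f_keep) >= rule$min_frl_dominance)
      status[j] <- if (dominant) "GROUP_SPECIFIC" else "VARIABLE"
    } else {
      shared <- length(f_keep) > 0L && length(v_keep) > 0L &&
        any(names(f_keep)[f_keep >= rule$min_frl_dominance] %in%
              names(v_keep)[v_keep >= rule$min_frl_dominance])
      status[j] <- if (shared) "SHARED_CONSERVED" else "VARIABLE"
    }
  }
  out <- data.frame(column = seq_len(n), status = status,
                    frl_set = frl_set, vl_set = vl_set,
                    frl_consensus = frl_cons,
                    frl_gap_fraction = fgap, vl_gap_fraction = vgap,
                    ancestral_state = NA_character_,
                    ancestral_conserved = NA)
  attr(out, "rule") <- rule
  class(out) <- c("column_classification", class(out))
  out
}

#' Score conservation of group-specific columns in an ancestral sequence
#'
#' A `GROUP_SPECIFIC` column counts as ancestral-conserved when the
#' ancestor's MAP (maximum a posteriori) state at the mapped site lies in
#' the column's noise-filtered FRL residue set. Columns that do not map to
#' an ancestral site (insertions relative to the ancestor) are specific but
#' not conserved.
#'
#' @param cols A `column_classification` from [classify_columns()].
#' @param anc An `ancestral_reconstruction` (see [reconstruct_marginal()]),
#'   or a plain character scalar ancestral sequence.
#' @param colmap Optional integer vector mapping alignment column to
#'   ancestral-sequence site (`NA` = unmapped); default: identity, which is
#'   correct when the ancestor was reconstructed on the same alignment
#'   columns.
#' @return List with `n_specific`, `n_conserved`, `fraction` (`NA` when no
#'   specific columns exist), and `classifications`, a copy of `cols` with
#'   `ancestral_state` and `ancestral_conserved` filled in.
#' @export
score_ancestral_conservation <- function(cols, anc, colmap = NULL) {
  stopifnot(inherits(cols, "column_classification"))
  anc_seq <- if (inherits(anc, "ancestral_reconstruction"))
    anc$map_sequence else as.character(anc)
  anc_chars <- strsplit(anc_seq, "", fixed = TRUE)[[1L]]
  if (is.null(colmap)) colmap <- seq_len(nrow(cols))
  spec <- which(cols$status == "GROUP_SPECIFIC")
  for (j in spec) {
    site <- if (j <= length(colmap)) colmap[j] else NA_integer_
    if (is.na(site) || site > length(anc_chars)) {
      cols$ancestral_conserved[j] <- FALSE
      next
    }
    state <- anc_chars[site]
    cols$ancestral_state[j] <- state
    fset <- strsplit(cols$frl_set[j], ",", fixed = TRUE)[[1L]]
    cols$ancestral_conserved[j] <- state %in% fset
  }
  n_specific <- length(spec)
  n_conserved <- sum(cols$ancestral_conserved[spec], na.rm = TRUE)
  list(n_specific = n_specific, n_conserved = n_conserved,
       fraction = if (n_specific > 0L) n_conserved / n_specific else NA_real_,
       classifications = cols)
}

#' Per-subunit summary of group-specific residues
#'
#' @param classified Named list, one element per subunit, each a list with
#'   elements `cols` (a `column_classification`) and `aln` (the
#'   corresponding [grouped_alignment()]).
#' @return Data frame `(subunit, n_specific, sequence_length,
#'   percent_specific)` sorted by descending percent. `sequence_length` is
#'   the ungapped FRL-consensus length: the number of columns where fewer
#'   than half of the FRL sequences have a gap.
#' @export
per_subunit_summary <- function(classified) {
  rows <- lapply(names(classified), function(nm) {
    cols <- classified[[nm]]$cols
    aln <- classified[[nm]]$aln
    frl <- aln$seq[aln$group == "FRL"]
    mat <- do.call(rbind, strsplit(frl, "", fixed = TRUE))
    len <- sum(colMeans(mat == "-") < 0.5)
    n_spec <- sum(cols$status == "GROUP_SPECIFIC")
    data.frame(subunit = nm, n_specific = n_spec, sequence_length = len,
               percent_specific = if (len > 0L) 100 * n_spec / len else 0)
  })
  out <- do.call(rbind, rows)
  out[order(-out$percent_specific, out$subunit), , drop = FALSE]
}

#' Write a classification table as TSV
#'
#' @param cols A `column_classification` (optionally already scored).
#' @param path Output file.
#' @param subunit Optional subunit name prepended as a column.
#' @export
write_classification <- function(cols, path, subunit = NA_character_) {
  out <- cbind(subunit = subunit, as.data.frame(cols))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
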