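# Alignment, label-table and identity utilities.

#' Construct a grouped alignment
#'
#' A grouped alignment couples an amino-acid multiple sequence alignment with
#' a per-sequence group label: `FRL` (far-red-light paralog), `VL`
#' (visible-light isoform) or `OUTGROUP`. It is the substrate of
#' [classify_columns()].
#'
#' @param seqs Named character vector of aligned sequences (residues, gap
#'   `-`, unknown `X`; case-insensitive). All must have equal length.
#' @param groups Named character vector (or factor) mapping every sequence id
#'   to one of `"FRL"`, `"VL"`, `"OUTGROUP"`.
#' @return An object of class `grouped_alignment` with elements `seq`
#'   (uppercase aligned strings), `group` (named character), and `n_columns`.
#' @examples
#' aln <- grouped_alignment(
#'   c(f1 = "MSLW-", f2 = "MSLW-", v1 = "MGLWA"),
#'   c(f1 = "FRL", f2 = "FRL", v1 = "VL"))
#' aln$n_columns
#' @export
grouped_alignment <- function(seqs, groups) {
  if (length(seqs) == 0L) stop("empty alignment")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named")
  if (anyDuplicated(ids))
    stop("duplicated sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("unequal lengths: record '", bad, "' has ", nchar(seqs[bad]),
         " columns, expected ", lens[1L])
  }
  groups <- setNames(toupper(as.character(groups)), names(groups))
  missing <- setdiff(ids, names(groups))
  if (length(missing))
    stop("missing group labels for: ", paste(missing, collapse = ", "))
  groups <- groups[ids]
  bad <- setdiff(unique(groups), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected FRL, VL or OUTGROUP)")
  structure(list(seq = seqs, group = groups, n_columns = unname(lens[1L])),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  tab <- table(factor(x$group, GROUP_LEVELS))
  cat("Grouped alignment: ", length(x$seq), " sequences x ",
      x$n_columns, " columns (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Read a group-label table
#'
#' Two tab-separated columns, `sequence_id<TAB>group`; lines starting with
#' `#` are comments. Group names are case-insensitive.
#'
#' @param path Path to the label table.
#' @return Named character vector of groups.
#' @export
read_group_labels <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "",
                    col.names = c("sequence_id", "group"))
  setNames(toupper(tab$group), tab$sequence_id)
}

#' Read an aligned FASTA file with group labels
#'
#' @param path Aligned FASTA file.
#' @param labels Either the path of a tab-separated label table (see
#'   [read_group_labels()]) or a named character vector of groups.
#' @return A [grouped_alignment()].
#' @export
read_alignment <- function(path, labels) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)))
    labels <- read_group_labels(labels)
  grouped_alignment(seqs, labels)
}

#' Write an alignment (or any named sequence set) as FASTA
#'
#' @param x A `grouped_alignment` or named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_alignment <- function(x, path, width = 60L) {
  seqs <- if (inherits(x, "grouped_alignment")) x$seq else x
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write a group-label table
#'
#' @param aln A `grouped_alignment`.
#' @param path Output file.
#' @export
write_group_labels <- function(aln, path) {
  write.table(data.frame(names(aln$seq), aln$group),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map alignment columns to ungapped sequence positions
#'
#' Columns where the sequence has a gap are absent from the map. Both
#' coordinates are 1-based.
#'
#' @param aln A `grouped_alignment`.
#' @param id Sequence id.
#' @return Data frame with columns `column` and `position`, strictly
#'   increasing in both.
#' @export
column_map <- function(aln, id) {
  if (!id %in% names(aln$seq)) stop("unknown sequence id: ", id)
  chars <- strsplit(aln$seq[[id]], "", fixed = TRUE)[[1L]]
  keep <- chars != "-"
  data.frame(column = which(keep), position = seq_len(sum(keep)))
}

# substitution matrix for identity-oriented global alignment:
# match +1, mismatch 0; X matches nothing.
.identity_submat <- function() {
  letters <- c(AA20, "X", "B", "Z", "J", "U", "O", "*")
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m["X", "X"] <- 0
  m
}

.align_global <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    type = "global", substitutionMatrix = .identity_submat(),
    gapOpening = 0, gapExtension = 1)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

#' Pairwise sequence identity
#'
#' In `aligned_columns` mode the two sequences must already be aligned to
#' equal length, and identity is counted over columns where neither has a
#' gap. In `shorter_length` mode a global pairwise alignment is computed
#' (match +1, mismatch 0, linear gap -1) and the identical-residue count is
#' normalized by the shorter ungapped length, the convention used for
#' redundancy reduction. `X` never counts as identical.
#'
#' @param a,b Sequences (character scalars, case-insensitive).
#' @param mode `"aligned_columns"` or `"shorter_length"`.
#' @return List with `n_identical`, `n_compared` and `fraction`.
#' @examples
#' pairwise_identity("MSLW", "MSLW")$fraction
#' @export
pairwise_identity <- function(a, b,
                              mode = c("aligned_columns", "shorter_length")) {
  mode <- match.arg(mode)
  a <- toupper(a); b <- toupper(b)
  if (mode == "aligned_columns") {
    if (nchar(a) != nchar(b))
      stop("aligned_columns mode requires equal-length sequences")
    ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
    keep <- ca != "-" & cb != "-"
    n_compared <- sum(keep)
    n_identical <- sum(ca[keep] == cb[keep] & ca[keep] != "X")
  } else {
    au <- gsub("-", "", a, fixed = TRUE)
    bu <- gsub("-", "", b, fixed = TRUE)
    if (nchar(au) == 0L || nchar(bu) == 0L)
      stop("cannot compute identity: empty sequence")
    al <- .align_global(au, bu)
    ca <- strsplit(al$a, "")[[1L]]; cb <- strsplit(al$b, "")[[1L]]
    n_identical <- sum(ca == cb & ca != "-" & ca != "X")
    n_compared <- min(nchar(au), nchar(bu))
  }
  if (n_compared == 0L)
    stop("identity undefined: no comparable positions")
  list(n_identical = n_identical, n_compared = n_compared,
       fraction = n_identical / n_compared)
}

#' Remove fragmented sequences
#'
#' Drops sequences shorter than `min_fraction` of the median ungapped
#' length, the curation step applied before redundancy reduction.
#'
#' @param seqs Named character vector of (unaligned) sequences.
#' @param min_fraction Length cutoff as a fraction of the median (default
#'   0.7).
#' @return The retained subset, original order preserved.
#' @export
filter_fragments <- function(seqs, min_fraction = 0.7) {
  if (length(seqs) == 0L) return(seqs)
  lens <- nchar(gsub("-", "", seqs, fixed = TRUE))
  seqs[lens >= min_fraction * stats::median(lens)]
}

#' Greedy redundancy reduction of a sequence set
#'
#' Sequences are sorted by length descending (ties broken by id), and each
#' is kept iff its identity (shorter-length normalization, see
#' [pairwise_identity()]) to every previously kept sequence is below
#' `threshold`. With the default 0.98 this reproduces curation of a set "to
#' 98% identity". Output order is the kept order.
#'
#' @param seqs Named character vector of unaligned sequences.
#' @param threshold Identity threshold in (0, 1].
#' @return The retained named subset.
#' @export
reduce_redundancy <- function(seqs, threshold = 0.98) {
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  if (length(seqs) == 0L) return(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  kept <- character(0)
  for (id in names(seqs)) {
    redundant <- FALSE
    for (k in kept) {
      if (pairwise_identity(seqs[[id]], seqs[[k]],
                            mode = "shorter_length")$fraction >= threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, id)
  }
  seqs[kept]
}
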