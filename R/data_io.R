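#' Validate and canonicalize a peptide sequence
#'
#' Strips whitespace, upper-cases, and checks that every character is one of
#' the 20 canonical amino-acid letters. Ambiguity codes (B, J, O, U, X, Z),
#' gaps and stop characters are rejected because they have no defined
#' composition, hydropathy or charge and would corrupt downstream features.
#'
#' @param seq character scalar, raw sequence.
#' @return canonical upper-case sequence.
#' @examples
#' validate_sequence(" adgf ")  # "ADGF"
#' @export
validate_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(gsub("[[:space:]]", "", seq))
  if (nchar(seq) == 0L) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L)
    stop(sprintf("non-canonical residue '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  seq
}

new_peptide_set <- function(id, seq, label = NA_integer_, name = NULL) {
  df <- data.frame(id = as.character(id), seq = as.character(seq),
                   label = as.integer(label), stringsAsFactors = FALSE)
  class(df) <- c("peptide_set", "data.frame")
  attr(df, "name") <- name
  df
}

#' @export
print.peptide_set <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf("peptide_set%s: %d peptides", if (is.null(nm)) ""
              else paste0(" '", nm, "'"), nrow(x)), "\n")
  if (!all(is.na(x$label))) {
    cc <- class_counts(x)
    cat(sprintf("  labels: %d ACP (1), %d non-ACP (0)\n",
                cc[["pos"]], cc[["neg"]]))
  }
  lens <- nchar(x$seq)
  cat(sprintf("  length: min %d, mean %.1f, max %d\n",
              min(lens), mean(lens), max(lens)))
  invisible(x)
}

#' Class counts of a labeled peptide set
#'
#' @param dataset a `peptide_set` with labels.
#' @return named integer vector with elements `pos` and `neg`.
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "peptide_set"))
  c(pos = sum(dataset$label == 1L, na.rm = TRUE),
    neg = sum(dataset$label == 0L, na.rm = TRUE))
}

#' Read a peptide FASTA file
#'
#' One record per peptide; sequences are upper-cased and validated against the
#' 20-letter alphabet. Records carrying non-canonical residues abort the read
#' by default; with `skip_invalid = TRUE` they are dropped with a warning
#' naming the record, which keeps composition features uncontaminated.
#'
#' @param path FASTA file path.
#' @param skip_invalid drop invalid records instead of failing.
#' @return a `peptide_set` (labels unset), record order preserved.
#' @export
read_fasta <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- as.character(aas)
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    res <- tryCatch(validate_sequence(seqs[i]), error = function(e) e)
    if (inherits(res, "error")) {
      if (!skip_invalid)
        stop(sprintf("record '%s': %s", ids[i], conditionMessage(res)))
      warning(sprintf("skipping record '%s': %s", ids[i],
                      conditionMessage(res)))
      keep[i] <- FALSE
    } else seqs[i] <- res
  }
  if (!any(keep)) stop("no valid records in ", path)
  new_peptide_set(ids[keep], seqs[keep])
}

#' Write a peptide set to FASTA
#'
#' @param dataset a `peptide_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "peptide_set"))
  x <- Biostrings::AAStringSet(dataset$seq)
  names(x) <- dataset$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Assemble a labeled dataset from a positive/negative FASTA pair
#'
#' Follows the usual ACP benchmark layout: one FASTA of anticancer peptides
#' (label 1) and one of non-ACPs (label 0). Duplicate identifiers across the
#' two files are auto-suffixed with a warning by default, since FASTA headers
#' in the wild are frequently reused.
#'
#' @param pos_path FASTA of positives (ACPs).
#' @param neg_path FASTA of negatives.
#' @param name dataset name, free text.
#' @param on_duplicate `"rename"` (default) or `"fail"`.
#' @param skip_invalid passed to [read_fasta()].
#' @return labeled `peptide_set`.
#' @export
load_labeled <- function(pos_path, neg_path, name = "dataset",
                         on_duplicate = c("rename", "fail"),
                         skip_invalid = FALSE) {
  on_duplicate <- match.arg(on_duplicate)
  pos <- read_fasta(pos_path, skip_invalid = skip_invalid)
  neg <- read_fasta(neg_path, skip_invalid = skip_invalid)
  if (nrow(pos) == 0L) stop("no positive samples")
  if (nrow(neg) == 0L) stop("no negative samples")
  ids <- c(pos$id, neg$id)
  if (anyDuplicated(ids)) {
    if (on_duplicate == "fail") stop("duplicate identifiers across files")
    warning("duplicate identifiers across files; auto-suffixing")
    ids <- make.unique(ids, sep = "_dup")
  }
  new_peptide_set(ids, c(pos$seq, neg$seq),
                  c(rep(1L, nrow(pos)), rep(0L, nrow(neg))), name = name)
}

#' Train/validation split of a labeled dataset
#'
#' Deterministic under `seed`. The stratified default samples each class
#' separately so the class ratio is preserved to within one peptide per class
#' (with balanced classes and fraction 0.8 a 250+250 set splits 200+200 /
#' 50+50).
#'
#' @param dataset labeled `peptide_set`.
#' @param train_fraction real in (0,1), default 0.8.
#' @param seed integer RNG seed.
#' @param stratified split within each class (default) or globally.
#' @return list with elements `train` and `validation`, both `peptide_set`s.
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1L,
                          stratified = TRUE) {
  stopifnot(inherits(dataset, "peptide_set"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("train_fraction must lie strictly inside (0, 1)")
  if (any(is.na(dataset$label))) stop("dataset must be fully labeled")
  n <- nrow(dataset)
  idx_train <- local({
    set.seed(as.integer(seed))
    if (stratified) {
      if (min(class_counts(dataset)) < 1L)
        stop("stratified split needs at least one member of each class")
      unlist(lapply(split(seq_len(n), dataset$label), function(ix) {
        sample(ix, round(length(ix) * train_fraction))
      }), use.names = FALSE)
    } else sample(seq_len(n), round(n * train_fraction))
  })
  idx_train <- sort(idx_train)
  nm <- attr(dataset, "name")
  take <- function(ix, suffix) {
    out <- new_peptide_set(dataset$id[ix], dataset$seq[ix],
                           dataset$label[ix],
                           name = if (is.null(nm)) suffix
                                  else paste(nm, suffix, sep = "/"))
    out
  }
  list(train = take(idx_train, "train"),
       validation = take(setdiff(seq_len(n), idx_train), "validation"))
}
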