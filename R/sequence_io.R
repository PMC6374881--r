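#' Read protein sequences from a FASTA file
#'
#' Parses a plain (optionally multi-line) FASTA file.  The identifier of
#' each record is the header token up to the first whitespace; sequence
#' lines are concatenated and uppercased.  Records are returned in file
#' order.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `residues`, one row per
#'   record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKLA", ">p2", "AC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  non_blank <- which(nzchar(trimws(lines)))
  if (length(non_blank) == 0L) stop("empty FASTA file: ", path)
  first <- non_blank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: sequence data before first header at line ",
         first, " of ", path)
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(seqs), "[ \t]"), `[`, character(1), 1L)
  data.frame(id = ids,
             residues = toupper(as.character(seqs)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove or reject non-canonical residues
#'
#' Benchmark sets occasionally carry ambiguity codes (B, Z, X, J), the
#' rare residues U and O, stop marks `*` or gap characters, none of which
#' the 20-letter AAC alphabet can represent.
#'
#' @param raw Residue string (uppercase).
#' @param policy `"drop"` silently removes non-canonical characters;
#'   `"reject"` raises an error naming the first offending character and
#'   its position.
#' @return Sanitized residue string over [AA_ALPHABET].
#' @export
sanitize_residues <- function(raw, policy = c("drop", "reject")) {
  policy <- match.arg(policy)
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  chars <- strsplit(raw, "")[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (!any(bad)) return(raw)
  if (policy == "reject") {
    i <- which(bad)[1L]
    stop("non-canonical residue '", chars[i], "' at position ", i)
  }
  out <- paste(chars[!bad], collapse = "")
  if (!nzchar(out)) stop("sequence empty after dropping non-canonical residues")
  out
}

#' Construct a labeled protein dataset
#'
#' @param ids Character vector of sequence identifiers (unique).
#' @param residues Character vector of residue strings, canonical alphabet.
#' @param labels Character vector of class labels.
#' @param class_names Optional explicit class ordering; defaults to the
#'   sorted set of distinct labels.
#' @return An object of class `"subloc_dataset"`: a list with elements
#'   `records` (data frame `id`, `residues`, `label`), `class_names` and
#'   `num`.
#' @export
subloc_dataset <- function(ids, residues, labels, class_names = NULL) {
  stopifnot(length(ids) == length(residues),
            length(ids) == length(labels))
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(residues))) stop("empty residue string in dataset")
  if (length(ids) < 2L) stop("a dataset needs at least 2 records")
  if (is.null(class_names)) class_names <- sort(unique(labels))
  if (!all(labels %in% class_names))
    stop("labels outside declared class set: ",
         paste(setdiff(labels, class_names), collapse = ", "))
  if (length(unique(labels)) < 2L)
    stop("a dataset needs at least 2 distinct classes")
  structure(list(
    records = data.frame(id = as.character(ids),
                         residues = as.character(residues),
                         label = as.character(labels),
                         stringsAsFactors = FALSE),
    class_names = class_names,
    num = length(ids)), class = "subloc_dataset")
}

#' @export
print.subloc_dataset <- function(x, ...) {
  cat("Labeled protein dataset:", x$num, "sequences,",
      length(x$class_names), "classes\n")
  print(class_counts(x))
  lens <- nchar(x$records$residues)
  cat("sequence length: min", min(lens), "max", max(lens), "\n")
  invisible(x)
}

#' Per-class sequence counts
#' @param dataset A [subloc_dataset].
#' @return Named integer vector in `class_names` order.
#' @export
class_counts <- function(dataset) {
  stopifnot(inherits(dataset, "subloc_dataset"))
  tab <- table(factor(dataset$records$label, levels = dataset$class_names))
  stats::setNames(as.integer(tab), names(tab))
}

#' Load a FASTA file plus a label manifest into a dataset
#'
#' The manifest is a two-column TSV (`id` TAB `class`); a header row is
#' recognised by a literal `id` first token.  Every FASTA id must appear
#' exactly once in the manifest.  Sequence order is file order and is
#' preserved by every downstream per-sequence output (jackknife folds
#' index into it).
#'
#' @param fasta Path to the FASTA file.
#' @param labels Path to the TSV label manifest.
#' @param sanitize Policy passed to [sanitize_residues()]; with the
#'   default `"drop"` each modified record is reported via a warning.
#' @return A [subloc_dataset].
#' @export
load_dataset <- function(fasta, labels, sanitize = c("drop", "reject")) {
  sanitize <- match.arg(sanitize)
  recs <- read_fasta(fasta)
  man <- utils::read.table(labels, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(man) < 2L) stop("label manifest must have two tab-separated columns")
  if (man[1L, 1L] == "id") man <- man[-1L, , drop = FALSE]
  if (anyDuplicated(man[[1L]]))
    stop("duplicate ids in label manifest: ",
         paste(unique(man[[1L]][duplicated(man[[1L]])]), collapse = ", "))
  missing <- setdiff(recs$id, man[[1L]])
  if (length(missing))
    stop("ids missing from label manifest: ", paste(missing, collapse = ", "))
  lab <- stats::setNames(man[[2L]], man[[1L]])[recs$id]
  clean <- vapply(recs$residues, sanitize_residues, character(1),
                  policy = sanitize, USE.NAMES = FALSE)
  changed <- clean != recs$residues
  if (any(changed))
    warning("dropped non-canonical residues in: ",
            paste(recs$id[changed], collapse = ", "))
  subloc_dataset(recs$id, clean, unname(lab))
}

#' Write a dataset back to FASTA + manifest
#'
#' Inverse of [load_dataset()]: re-loading the written pair yields the
#' identical records in identical order.
#'
#' @param dataset A [subloc_dataset].
#' @param fasta,labels Output paths.
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(dataset, fasta, labels) {
  stopifnot(inherits(dataset, "subloc_dataset"))
  r <- dataset$records
  writeLines(paste0(">", r$id, "\n", r$residues), fasta)
  writeLines(c("id\tclass", paste0(r$id, "\t", r$label)), labels)
  invisible(dataset)
}

#' Write a per-class count summary as TSV
#' @param dataset A [subloc_dataset].
#' @param path Output path.
#' @export
write_dataset_summary <- function(dataset, path) {
  counts <- class_counts(dataset)
  utils::write.table(data.frame(class = names(counts), count = counts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dataset)
}
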