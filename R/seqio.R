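#' Sequence record tables
#'
#' Throughout the package a collection of DNA sequences is an ordinary tibble
#' with one row per record and columns:
#' \describe{
#'   \item{id}{unique character identifier}
#'   \item{bases}{DNA string over the alphabet A, C, G, T}
#'   \item{group}{phenotype group, `"group1"` or `"group2"` (may be `NA`
#'     until groups are assigned)}
#'   \item{count}{positive integer abundance (dereplication multiplicity)}
#'   \item{events}{number of substitution events since the ancestor
#'     (simulator bookkeeping; 0 for external data)}
#' }
#'
#' `seq_tbl()` builds such a tibble from vectors and validates it;
#' `validate_seqs()` checks an existing one and returns it invisibly.
#'
#' Ambiguity codes (N, R, Y, ...) and gap characters are rejected rather than
#' coerced: identity semantics for non-ACGT characters are undefined here.
#'
#' @param id character vector of unique identifiers.
#' @param bases character vector of ACGT strings (lowercase is accepted and
#'   uppercased).
#' @param group optional group labels (`"group1"`/`"group2"` or 1/2).
#' @param count positive integer abundances, recycled.
#' @param events non-negative integer substitution-event counts, recycled.
#' @return A validated sequence tibble.
#' @examples
#' seq_tbl(c("a", "b"), c("ACGT", "GGCC"))
#' @export
seq_tbl <- function(id, bases, group = NA_character_, count = 1L,
                    events = 0L) {
  records <- tibble(
    id = as.character(id),
    bases = toupper(as.character(bases)),
    group = normalize_group(group),
    count = as.integer(count),
    events = as.integer(events)
  )
  validate_seqs(records)
  records
}

normalize_group <- function(group) {
  if (all(is.na(group))) return(rep(NA_character_, length(group)))
  g <- as.character(group)
  g[g == "1"] <- "group1"
  g[g == "2"] <- "group2"
  bad <- !is.na(g) & !g %in% c("group1", "group2")
  if (any(bad)) {
    abort(sprintf("invalid group label(s): %s",
                  paste(unique(g[bad]), collapse = ", ")))
  }
  g
}

#' @rdname seq_tbl
#' @param records a sequence tibble.
#' @export
validate_seqs <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("id", "bases", "count")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("sequence table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  dup <- records$id[duplicated(records$id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sequence id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  check_bases(records$bases, records$id)
  if (any(records$count < 1)) abort("counts must be >= 1")
  if ("events" %in% names(records) && any(records$events < 0)) {
    abort("events must be >= 0")
  }
  invisible(records)
}

check_bases <- function(bases, id = NULL) {
  if (any(is.na(bases)) || any(nchar(bases) == 0)) {
    abort("empty sequence(s) are not allowed")
  }
  bad <- regexpr("[^ACGT]", bases)
  hit <- which(bad > 0)
  if (length(hit) > 0) {
    i <- hit[1]
    who <- if (is.null(id)) sprintf("sequence %d", i) else
      sprintf("sequence '%s'", id[i])
    abort(sprintf(
      "non-ACGT character '%s' at position %d of %s (ambiguity codes and gaps are rejected)",
      substr(bases[i], bad[i], bad[i]), bad[i], who))
  }
  invisible(bases)
}

#' Read a FASTA file into a sequence tibble
#'
#' Records are returned in file order, multi-line sequences are joined,
#' lowercase bases are uppercased, and the first whitespace-delimited token
#' of each header becomes the id. Duplicate ids and non-ACGT characters are
#' errors; an empty file yields an empty tibble.
#'
#' @param path path to a plain FASTA file.
#' @return A sequence tibble (see [seq_tbl()]) with `group = NA`,
#'   `count = 1`, `events = 0`.
#' @seealso [write_fasta()], [assign_groups()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (file.size(path) == 0) {
    return(seq_tbl(character(), character()))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) return(seq_tbl(character(), character()))
  ids <- sub("\\s.*$", "", names(set))
  seq_tbl(id = ids, bases = as.character(set))
}

#' Write a sequence tibble to FASTA
#'
#' A round trip through [read_fasta()] preserves ids, order and bases
#' exactly. Group, count and events columns are not serialized; use
#' [write_generation_set()] when that bookkeeping must be kept.
#'
#' @param records a sequence tibble.
#' @param path output file path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  validate_seqs(records)
  stopifnot(.is_count(width))
  set <- Biostrings::DNAStringSet(setNames(records$bases, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' GC fraction and GC-content group assignment
#'
#' `gc_fraction()` returns (#G + #C) / length for each sequence.
#' `assign_group()` maps a sequence to `"group1"` when its GC fraction is
#' at most 50% and `"group2"` otherwise; the boundary is evaluated in integer
#' arithmetic (2 * GC-count vs length) so the "at most" rule is exact, and a
#' sequence with exactly 50% GC is group 1.
#'
#' @param bases character vector of ACGT strings.
#' @return `gc_fraction()`: numeric vector in `[0, 1]`; `assign_group()`:
#'   character vector of `"group1"`/`"group2"`.
#' @examples
#' gc_fraction(c("ATGC", "GGGG"))
#' assign_group("ATGC") # exactly 50% GC -> group1
#' @export
gc_fraction <- function(bases) {
  check_bases(toupper(bases))
  gc_count(toupper(bases)) / nchar(bases)
}

gc_count <- function(bases) {
  nchar(gsub("[AT]", "", bases))
}

#' @rdname gc_fraction
#' @export
assign_group <- function(bases) {
  bases <- toupper(bases)
  check_bases(bases)
  ifelse(2L * gc_count(bases) <= nchar(bases), "group1", "group2")
}

#' Assign phenotype groups to a sequence tibble
#'
#' By default groups are derived from GC content (see [assign_group()]).
#' Alternatively a two-column tab-separated id-to-group file (values 1 or 2)
#' read with [read_group_map()] supplies external phenotype labels.
#'
#' @param records a sequence tibble.
#' @param map optional group map tibble from [read_group_map()].
#' @return `records` with the `group` column filled in.
#' @export
assign_groups <- function(records, map = NULL) {
  validate_seqs(records)
  if (is.null(map)) {
    records$group <- assign_group(records$bases)
  } else {
    idx <- match(records$id, map$id)
    if (anyNA(idx)) {
      abort(sprintf("group map lacks id(s): %s",
                    paste(utils::head(records$id[is.na(idx)], 5),
                          collapse = ", ")))
    }
    records$group <- map$group[idx]
  }
  records
}

#' @rdname assign_groups
#' @param path path to a tab-separated file with lines `<seq_id>\t<1|2>`.
#' @export
read_group_map <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("id", "group"))
  tibble(id = raw$id, group = normalize_group(raw$group))
}

#' Dereplicate identical sequences
#'
#' Collapses records with identical bases into one record whose count is the
#' sum of the input counts, keeping the id, events and position of the first
#' occurrence. Total abundance is conserved and the operation is idempotent.
#'
#' @param records a sequence tibble.
#' @return A dereplicated sequence tibble.
#' @export
dereplicate <- function(records) {
  validate_seqs(records)
  if (nrow(records) == 0) return(records)
  first <- !duplicated(records$bases)
  counts <- tapply(records$count, factor(records$bases,
                                         levels = records$bases[first]),
                   sum)
  out <- records[first, , drop = FALSE]
  out$count <- as.integer(counts[out$bases])
  out
}
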