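#' Read an aligned FASTA file
#'
#' Reads equal-length aligned sequences (e.g. a 16S, COI or 28S barcode
#' alignment) into a character-matrix alignment object. Symbols are
#' uppercased; anything outside `A C G T -` and the IUPAC ambiguity codes
#' is mapped to `N` with a warning. Ambiguity codes are kept as-is in the
#' matrix but are treated as missing by the site filter (see
#' [complete_deletion()]).
#'
#' @param path path to an aligned FASTA file.
#' @param locus locus tag, one of `"16S"`, `"COI"`, `"28S"`, `"other"`.
#' @param locality_map optional named character vector mapping sequence ids
#'   to locality labels (e.g. the a-priori geographic regions used when
#'   classifying haplotypes as shared or private).
#' @return An object of class `dna_alignment`: list with `locus`, `ids`,
#'   `matrix` (n x L character), `locality`.
#' @export
read_alignment <- function(path, locus = "other", locality_map = NULL) {
  if (!file.exists(path)) stop_config(sprintf("FASTA file not found: %s", path))
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0) stop_validation("empty FASTA file")
  lens <- lengths(recs)
  if (length(unique(lens)) != 1) {
    stop_validation(sprintf(
      "ragged alignment: sequence lengths %s differ",
      paste(unique(lens), collapse = ", ")))
  }
  mat <- toupper(as.character(as.matrix(recs)))
  dna_alignment(mat, locus = locus, locality = locality_map)
}

#' Construct an alignment object from a character matrix
#'
#' @param mat character matrix (rows = sequences, rownames = ids) or a
#'   named character vector of equal-length sequence strings.
#' @inheritParams read_alignment
#' @param locality optional named character vector id -> locality label.
#' @return A `dna_alignment` object.
#' @export
dna_alignment <- function(mat, locus = "other", locality = NULL) {
  if (is.character(mat) && is.null(dim(mat))) {
    if (length(unique(nchar(mat))) != 1) {
      stop_validation("ragged alignment: sequence strings differ in length")
    }
    ids <- names(mat)
    mat <- do.call(rbind, strsplit(mat, ""))
    rownames(mat) <- ids
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("seq%d", seq_len(nrow(mat)))
  }
  ids <- rownames(mat)
  if (anyDuplicated(ids)) {
    stop_validation(sprintf("duplicate sequence ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  mat <- toupper(mat)
  allowed <- c("A", "C", "G", "T", "-",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "?")
  unknown <- !(mat %in% allowed)
  if (any(unknown)) {
    warn_flag(sprintf("%d unknown symbol(s) mapped to N", sum(unknown)),
              class = "hadalrange_unknown_symbols")
    mat[unknown] <- "N"
  }
  mat[mat == "?"] <- "N"
  loc <- setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(locality)) {
    hit <- intersect(ids, names(locality))
    loc[hit] <- locality[hit]
  }
  structure(list(locus = locus, ids = ids, matrix = mat, locality = loc),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment (%s): %d sequences x %d sites\n",
              x$locus, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Site filter by complete deletion
#'
#' Retains exactly the alignment columns where every sequence carries an
#' unambiguous base (`A`, `C`, `G` or `T`); any column containing a gap,
#' `N` or an IUPAC ambiguity code in any sequence is dropped. This is the
#' default missing-data convention for all diversity statistics, haplotype
#' collapsing and distance computation, so segregating sites, mean pairwise
#' differences and per-site diversity share one site universe.
#'
#' @param alignment a `dna_alignment`.
#' @return An object of class `site_filter`: `retained` (0-based column
#'   indices, strictly increasing), `L_retained`, `mode = "complete"`.
#' @export
complete_deletion <- function(alignment) {
  m <- alignment$matrix
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  keep <- which(colSums(ok) == nrow(m))
  if (length(keep) == 0) {
    stop_validation("complete deletion removed every column; statistics undefined")
  }
  structure(list(retained = as.integer(keep - 1L),
                 L_retained = length(keep),
                 mode = "complete"),
            class = "site_filter")
}

#' @export
print.site_filter <- function(x, ...) {
  cat(sprintf("Site filter (%s deletion): %d columns retained\n",
              x$mode, x$L_retained))
  invisible(x)
}

## n x L_retained matrix restricted to the filter's columns.
filtered_matrix <- function(alignment, filter = NULL) {
  if (is.null(filter)) filter <- complete_deletion(alignment)
  alignment$matrix[, filter$retained + 1L, drop = FALSE]
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical over the retained columns share one haplotype.
#' Haplotype ids (`H1`, `H2`, ...) are assigned in order of first
#' occurrence in the alignment; each haplotype records its frequency,
#' member sequence ids and the set of locality labels of its members.
#'
#' @param alignment a `dna_alignment`.
#' @param filter a `site_filter` from the same alignment; defaults to
#'   [complete_deletion()].
#' @return An object of class `haplotype_table`: data frame `haplotypes`
#'   (haplotype_id, sequence, frequency) plus list-columns of members and
#'   localities, and scalars `n` (total sequences) and `H`.
#' @export
collapse_haplotypes <- function(alignment, filter = NULL) {
  m <- filtered_matrix(alignment, filter)
  keys <- apply(m, 1, paste, collapse = "")
  first <- !duplicated(keys)
  reps <- keys[first]
  idx <- match(keys, reps)
  hap_id <- sprintf("H%d", seq_along(reps))
  members <- split(alignment$ids, idx)
  localities <- lapply(members, function(ids) {
    sort(unique(alignment$locality[ids][!is.na(alignment$locality[ids])]))
  })
  unlocalized <- lapply(members, function(ids) {
    ids[is.na(alignment$locality[ids])]
  })
  tab <- data.frame(haplotype_id = hap_id,
                    sequence = reps,
                    frequency = as.integer(tabulate(idx, nbins = length(reps))),
                    stringsAsFactors = FALSE)
  tab$members <- unname(members)
  tab$localities <- unname(localities)
  tab$unlocalized <- unname(unlocalized)
  structure(list(haplotypes = tab, n = nrow(m), H = length(reps),
                 locus = alignment$locus),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype table (%s): H = %d haplotypes from n = %d sequences\n",
              x$locus, x$H, x$n))
  df <- x$haplotypes
  cat(paste(sprintf("  %s: n=%d, localities={%s}", df$haplotype_id,
                    df$frequency,
                    vapply(df$localities, paste, "", collapse = ",")),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Write a haplotype table to CSV
#'
#' @param table a `haplotype_table`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_haplotype_table <- function(table, path) {
  df <- table$haplotypes
  out <- data.frame(haplotype_id = df$haplotype_id,
                    frequency = df$frequency,
                    localities = vapply(df$localities, paste, "", collapse = ";"),
                    members = vapply(df$members, paste, "", collapse = ";"),
                    sequence = df$sequence,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
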