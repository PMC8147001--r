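# Protein alphabet used throughout: the 20 standard residues plus '-' (gap)
# and 'X' (unknown). Everything else is a hard error — silent coercion of
# malformed ortholog sets causes far worse failures downstream.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
ALPHABET <- c(AA_LETTERS, "-", "X")

check_alphabet <- function(residues, taxon = "<sequence>") {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% ALPHABET))
  if (length(bad) > 0) {
    stop(sprintf(
      "alphabet error: illegal residue '%s' at position %d in '%s'",
      chars[bad[1]], bad[1], taxon
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a single-locus alignment
#'
#' A `locus_alignment` holds one locus' orthologous aligned protein
#' sequences keyed by taxon. All member strings must have identical length
#' and use only the 20 amino-acid letters plus `-` (gap) and `X` (unknown).
#'
#' @param locus Locus name (e.g. a CatSper subunit).
#' @param members Named character vector, taxon -> aligned residue string.
#' @return An object of class `locus_alignment` with fields `locus`,
#'   `members` and `length` (alignment columns).
#' @export
locus_alignment <- function(locus, members) {
  if (length(members) == 0 || is.null(names(members)) || any(names(members) == ""))
    stop("locus_alignment: members must be a non-empty named character vector", call. = FALSE)
  if (anyDuplicated(names(members)))
    stop(sprintf("duplicate taxon in locus '%s': %s", locus,
                 names(members)[duplicated(names(members))][1]), call. = FALSE)
  members <- toupper(members)
  if (any(nchar(members) == 0))
    stop("locus_alignment: empty residue string", call. = FALSE)
  lens <- nchar(members)
  if (length(unique(lens)) != 1)
    stop(sprintf(
      "alignment-format error in locus '%s': unequal sequence lengths (%s)",
      locus, paste(unique(lens), collapse = ", ")
    ), call. = FALSE)
  for (i in seq_along(members)) check_alphabet(members[[i]], names(members)[i])
  structure(
    list(locus = locus, members = members, length = unname(lens[1])),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment '%s': %d taxa x %d columns>\n",
              x$locus, length(x$members), x$length))
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' Taxon names are parsed from the header up to the first whitespace.
#' In alignment mode (default) all records must have equal length.
#'
#' @param path FASTA file path.
#' @param locus Locus name; defaults to the file name without extension.
#' @param aligned Require equal record lengths (default `TRUE`).
#' @return A [locus_alignment].
#' @export
read_fasta <- function(path, locus = NULL, aligned = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop(sprintf("empty FASTA: %s", path), call. = FALSE)
  members <- as.character(set)
  names(members) <- sub("\\s.*$", "", names(set))
  if (!aligned) {
    members <- toupper(members)
    for (i in seq_along(members)) check_alphabet(members[[i]], names(members)[i])
    return(structure(list(locus = locus, members = members, length = NA_integer_),
                     class = "locus_alignment"))
  }
  locus_alignment(locus, members)
}

#' Write a locus alignment as FASTA
#'
#' @param aln A [locus_alignment].
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(aln, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (taxon in names(aln$members)) {
    writeLines(paste0(">", taxon), con)
    seq <- aln$members[[taxon]]
    starts <- seq(1, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1, nchar(seq))), con)
  }
  invisible(path)
}

#' Concatenate locus alignments into a partitioned supermatrix
#'
#' Joins per-locus alignments column-wise in the order given, recording
#' 0-based half-open partition ranges. With `missing_policy = "drop_taxon"`
#' (default) only taxa present in every listed locus are kept — this
#' mirrors analyses that either include all ten CatSper subunits or drop
#' CatSperz so that species lacking its annotation can be retained. With
#' `"gap_fill"`, a taxon absent from a locus receives an all-gap block.
#'
#' @param loci List of [locus_alignment] objects.
#' @param order Character vector of locus names defining column order;
#'   defaults to the order of `loci`.
#' @param missing_policy `"drop_taxon"` or `"gap_fill"`.
#' @return An object of class `concat_alignment` with fields `order`,
#'   `taxa`, `rows` (taxon -> residue string) and `partitions` (data frame
#'   with `locus`, `start`, `end`).
#' @export
concatenate <- function(loci, order = NULL,
                        missing_policy = c("drop_taxon", "gap_fill")) {
  missing_policy <- match.arg(missing_policy)
  names(loci) <- vapply(loci, function(a) a$locus, character(1))
  if (is.null(order)) order <- names(loci)
  missing_loci <- setdiff(order, names(loci))
  if (length(missing_loci) > 0)
    stop(sprintf("order names unknown loci: %s", paste(missing_loci, collapse = ", ")),
         call. = FALSE)
  loci <- loci[order]

  taxa_sets <- lapply(loci, function(a) names(a$members))
  if (missing_policy == "drop_taxon") {
    taxa <- Reduce(intersect, taxa_sets)
    if (length(taxa) == 0)
      stop("empty-concatenation error: no taxon is present in every listed locus",
           call. = FALSE)
  } else {
    taxa <- Reduce(union, taxa_sets)
  }

  lens <- vapply(loci, function(a) a$length, integer(1))
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  partitions <- data.frame(locus = order, start = as.integer(starts),
                           end = as.integer(ends), stringsAsFactors = FALSE)

  rows <- vapply(taxa, function(taxon) {
    paste(vapply(loci, function(a) {
      if (taxon %in% names(a$members)) a$members[[taxon]]
      else strrep("-", a$length)
    }, character(1)), collapse = "")
  }, character(1))
  names(rows) <- taxa

  structure(
    list(order = order, taxa = taxa, rows = rows, partitions = partitions),
    class = "concat_alignment"
  )
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment: %d taxa x %d columns, %d loci (%s)>\n",
              length(x$taxa), alignment_length(x), length(x$order),
              paste(x$order, collapse = "-")))
  invisible(x)
}

#' Total column count of an alignment
#' @param aln A `locus_alignment` or `concat_alignment`.
#' @return Integer number of columns.
#' @export
alignment_length <- function(aln) {
  if (inherits(aln, "concat_alignment")) return(max(aln$partitions$end))
  aln$length
}

# Rows of any alignment as a named character vector (taxon -> string).
alignment_rows <- function(aln) {
  if (inherits(aln, "concat_alignment")) aln$rows else aln$members
}

# Residue character matrix (taxa x columns), computed once per analysis.
alignment_matrix <- function(aln) {
  rows <- alignment_rows(aln)
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

#' Read a taxon-to-clade membership table
#'
#' Two-column tab-separated file (taxon, clade), no header by default.
#'
#' @param path TSV path.
#' @param header Whether the file has a header row.
#' @return Named character vector: taxon -> clade label.
#' @export
read_clademap <- function(path, header = FALSE) {
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("clade map must have two columns (taxon, clade)", call. = FALSE)
  taxa <- as.character(tab[[1]])
  if (anyDuplicated(taxa))
    stop(sprintf("duplicate-key error in clade map: %s",
                 taxa[duplicated(taxa)][1]), call. = FALSE)
  stats::setNames(as.character(tab[[2]]), taxa)
}

#' Write a taxon-to-clade membership table
#' @param clades Named character vector, taxon -> clade.
#' @param path Output TSV path.
#' @export
write_clademap <- function(clades, path) {
  utils::write.table(
    data.frame(taxon = names(clades), clade = unname(clades)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write a data frame as TSV
#' @param table Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tree in Newick format
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file path.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
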