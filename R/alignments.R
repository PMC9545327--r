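#' Locus alignment objects
#'
#' A `locus_aln` holds one aligned locus as a character matrix (rows =
#' allele sequences, columns = alignment sites) over the alphabet
#' `A C G T - N`. Phased nuclear data carry two rows per diploid
#' individual, labelled `<individual>_a1` and `<individual>_a2`; haploid
#' mtDNA carries one row per individual labelled with the bare individual
#' name.
#'
#' @param locus_id Single locus label.
#' @param seqs Named character vector of equal-length sequences, or a
#'   character matrix with one row per sequence (rownames = labels).
#' @return An object of class `locus_aln`: a list with elements
#'   `locus_id`, `mat` (character matrix) and `length` (alignment columns).
#' @examples
#' aln <- locus_aln("uce-1", c(ind1_a1 = "ACGT", ind1_a2 = "ACGA"))
#' aln$length
#' @export
locus_aln <- function(locus_id, seqs) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      abort("sequence labels must be present and unique")
    }
    n <- nchar(seqs)
    if (length(unique(n)) != 1L) {
      abort(sprintf("ragged alignment in locus '%s': sequence lengths %s",
                    locus_id, paste(unique(n), collapse = ", ")))
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  if (ncol(mat) < 1L) abort(sprintf("locus '%s' has zero columns", locus_id))
  bad <- !(mat %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) {
    warn(sprintf("locus '%s': %d characters outside {A,C,G,T,-,N} set to N",
                 locus_id, sum(bad)))
    mat[bad] <- "N"
  }
  structure(list(locus_id = locus_id, mat = mat, length = ncol(mat)),
            class = "locus_aln")
}

#' @export
print.locus_aln <- function(x, ...) {
  cat(sprintf("<locus_aln> %s: %d sequences x %d sites\n",
              x$locus_id, nrow(x$mat), x$length))
  invisible(x)
}

aln_labels <- function(aln) rownames(aln$mat)

# Individuals present in an alignment: allele labels "<ind>_a1"/"<ind>_a2"
# collapse to "<ind>"; bare labels (mtDNA) pass through. An individual is
# present only if at least one of its sequences has >= 1 unambiguous base.
aln_individuals <- function(aln) {
  lab <- aln_labels(aln)
  has_base <- rowSums(aln$mat == "A" | aln$mat == "C" |
                        aln$mat == "G" | aln$mat == "T") > 0
  unique(strip_allele(lab[has_base]))
}

strip_allele <- function(x) sub("_a[12]$", "", x)

#' Read a directory of per-locus FASTA alignments
#'
#' Each FASTA file becomes one [locus_aln()] named after the file (without
#' extension). Lower-case bases are upper-cased; characters outside
#' `A C G T - N` are converted to `N` with a warning. Files whose sequences
#' differ in length raise an error naming the file.
#'
#' @param path Directory containing `.fasta`/`.fa` files.
#' @return Named list of `locus_aln` objects (empty list for an empty
#'   directory).
#' @seealso [write_locus_fasta_dir()], [filter_by_completeness()]
#' @export
read_locus_fasta_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  alns <- lapply(files, function(f) {
    ss <- Biostrings::readBStringSet(f)
    locus_id <- sub("\\.(fa|fasta)$", "", basename(f))
    seqs <- setNames(as.character(ss), names(ss))
    if (length(unique(nchar(seqs))) > 1L) {
      abort(sprintf("ragged alignment in file '%s'", f))
    }
    locus_aln(locus_id, seqs)
  })
  names(alns) <- vapply(alns, function(a) a$locus_id, character(1))
  alns
}

#' Write per-locus alignments as FASTA files
#'
#' @param alignments Named list of [locus_aln()] objects.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_locus_fasta_dir <- function(alignments, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (aln in alignments) {
    seqs <- apply(aln$mat, 1, paste, collapse = "")
    ss <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(ss, file.path(path, paste0(aln$locus_id, ".fasta")))
  }
  invisible(path)
}

#' Species map construction and IO
#'
#' The species map ties each sequenced individual to its species, host fig
#' and the mean foundress number of that host (NA where unknown).
#'
#' @param individual,species Character vectors (equal length).
#' @param host Optional host label per individual.
#' @param foundress Optional mean foundress count per individual's host.
#' @return A tibble with columns `individual`, `species`, `host`,
#'   `foundress`.
#' @examples
#' species_map(c("w1", "w2"), c("spA", "spA"))
#' @export
species_map <- function(individual, species, host = NA_character_,
                        foundress = NA_real_) {
  if (anyDuplicated(individual)) abort("individuals must be unique")
  tibble(individual = as.character(individual),
         species = as.character(species),
         host = as.character(host),
         foundress = as.numeric(foundress))
}

#' @rdname species_map
#' @param path TSV file with columns individual, species, host, foundress.
#' @export
read_species_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  species_map(df$individual, df$species,
              host = df$host %||% NA_character_,
              foundress = df$foundress %||% NA_real_)
}

#' @rdname species_map
#' @param map A species-map tibble.
#' @export
write_species_map <- function(map, path) {
  readr::write_tsv(map, path)
  invisible(path)
}

#' Retain loci sampled for a minimum fraction of individuals
#'
#' Mirrors the standard phylogenomic completeness filter: a locus is kept
#' when the number of distinct individuals with at least one allele
#' present is at least `threshold` times the total number of individuals
#' in the species map (boundary inclusive, so 7 of 10 passes at 0.70).
#' Presence counts individuals, not alleles.
#'
#' @param alignments Named list of [locus_aln()] objects.
#' @param map Species map tibble (defines the individual universe).
#' @param threshold Minimum fraction of individuals, in (0, 1]. Default
#'   0.70.
#' @param quiet Suppress the kept/dropped message.
#' @return The retained subset of `alignments`, with attribute
#'   `filter_counts` = c(kept, dropped).
#' @export
filter_by_completeness <- function(alignments, map, threshold = 0.70,
                                   quiet = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  n_total <- length(unique(map$individual))
  keep <- vapply(alignments, function(aln) {
    pres <- intersect(aln_individuals(aln), map$individual)
    length(pres) / n_total >= threshold
  }, logical(1))
  out <- alignments[keep]
  if (!quiet) {
    message(sprintf("completeness filter (%.0f%%): kept %d, dropped %d loci",
                    100 * threshold, sum(keep), sum(!keep)))
  }
  attr(out, "filter_counts") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}
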