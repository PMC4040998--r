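# Plain-text readers and writers for the pipeline's exchange formats.
# Coverage and presence tables travel as TSV, alignments as FASTA, truth
# sets and test reports as JSON.

#' Write / read a window coverage track as TSV
#'
#' Columns: strain, replicon, window_start (0-based, half-open windows),
#' raw_count, gc_fraction.
#'
#' @param track coverage track data.frame
#' @param path file path
#' @return `read_coverage_tsv` returns the track with an empty
#'   `corrected_count` column ready for [gc_correct_coverage()]
#' @export
write_coverage_tsv <- function(track, path) {
  utils::write.table(
    track[, c("strain", "replicon", "window_start", "raw_count",
              "gc_fraction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @export
read_coverage_tsv <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  tr$corrected_count <- NA_real_
  tr
}

#' Write / read a gene presence/absence matrix as TSV
#'
#' Two files: `<path>` holds the 0/1 matrix (clusters x strains, first
#' column `cluster_id`, second `species_of_strain` header row encoded in a
#' companion metadata file `<path>.meta` with cluster metadata and the
#' strain -> species map).
#'
#' @param matrix a `gene_presence_matrix`
#' @param path base file path
#' @return `read_presence_matrix` returns a `gene_presence_matrix` (without
#'   per-strain gene order, which the TSV format does not carry)
#' @export
write_presence_matrix <- function(matrix, path) {
  m <- data.frame(cluster_id = rownames(matrix$presence),
                  matrix$presence * 1L, check.names = FALSE)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(species = as.list(matrix$species), meta = matrix$meta)
  jsonlite::write_json(meta, paste0(path, ".meta"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  m <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  pres <- as.matrix(m[, -1, drop = FALSE]) > 0
  rownames(pres) <- m$cluster_id
  meta <- jsonlite::read_json(paste0(path, ".meta"), simplifyVector = TRUE)
  out <- list(presence = pres,
              species = unlist(meta$species)[colnames(pres)],
              meta = as.data.frame(meta$meta, stringsAsFactors = FALSE),
              order = NULL)
  class(out) <- "gene_presence_matrix"
  out
}

#' Write / read a codon alignment as FASTA
#'
#' Ingroup and outgroup membership is encoded in the headers as
#' `<name> ingroup` / `<name> outgroup`.
#'
#' @param aln a `codon_alignment`
#' @param path file path
#' @return `read_codon_alignment` returns a `codon_alignment`
#' @export
write_codon_alignment <- function(aln, path) {
  roles <- ifelse(names(aln$seqs) %in% aln$ingroup, "ingroup", "outgroup")
  seqinr::write.fasta(as.list(aln$seqs), paste(names(aln$seqs), roles),
                      path, as.string = TRUE, nbchar = 80)
  invisible(path)
}

#' @rdname write_codon_alignment
#' @param gene gene id to record on the object
#' @export
read_codon_alignment <- function(path, gene = NULL) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           whole.header = TRUE)
  headers <- names(fa)
  parts <- strsplit(headers, "\\s+")
  nm <- vapply(parts, `[[`, character(1), 1)
  role <- vapply(parts, function(p) if (length(p) > 1) p[2] else "ingroup",
                 character(1))
  seqs <- stats::setNames(toupper(unlist(fa)), nm)
  aln <- list(gene = gene %||% sub("\\.[^.]*$", "", basename(path)),
              seqs = seqs, ingroup = nm[role == "ingroup"],
              outgroup = nm[role == "outgroup"])
  class(aln) <- "codon_alignment"
  aln
}

#' Write a truth set (or any result list) as JSON
#'
#' @param x list of data.frames/vectors
#' @param path file path
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a frequency spectrum as TSV
#'
#' Columns: class, n, bin, count, weight, proportion.
#'
#' @param spectrum a `freq_spectrum`
#' @param path file path
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  nb <- length(spectrum$counts)
  props <- c(spectrum$proportions,
             rep(NA_real_, nb - length(spectrum$proportions)))
  utils::write.table(
    data.frame(class = spectrum$class, n = spectrum$n,
               bin = as.integer(names(spectrum$counts)),
               count = as.numeric(spectrum$counts),
               weight = as.numeric(spectrum$weights),
               proportion = as.numeric(props)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
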