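#' Per-cell per-strand mtDNA base-count tensor
#'
#' Container for raw mitochondrial read counts resolved by cell, genomic
#' position, base and strand, the substrate from which heteroplasmy and all
#' variant statistics are computed. Only positions of interest (typically
#' candidate variant sites) need to be stored; positions are 1-based on the
#' 16,569 bp mitochondrial genome.
#'
#' @param counts integer array with dimensions
#'   `(cells, positions, 4 bases, 2 strands)`; bases ordered A, C, G, T and
#'   strands plus, minus.
#' @param barcodes character vector of cell barcodes (unique).
#' @param positions integer vector of 1-based mtDNA positions.
#' @param ref character vector of reference bases, one per position.
#' @return An object of class `mt_tensor`.
#' @export
mt_tensor <- function(counts, barcodes, positions, ref) {
  stopifnot(
    length(dim(counts)) == 4,
    dim(counts)[1] == length(barcodes),
    dim(counts)[2] == length(positions),
    dim(counts)[3] == 4, dim(counts)[4] == 2,
    !anyDuplicated(barcodes),
    all(positions >= 1L), all(positions <= MT_GENOME_LENGTH),
    length(ref) == length(positions), all(ref %in% BASES)
  )
  if (any(counts < 0)) stop("negative read counts")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(barcodes, as.character(positions), BASES, STRANDS)
  structure(
    list(counts = counts, barcodes = barcodes,
         positions = as.integer(positions), ref = ref),
    class = "mt_tensor"
  )
}

#' @export
print.mt_tensor <- function(x, ...) {
  cat(sprintf("<mt_tensor> %d cells x %d mtDNA positions (total reads: %s)\n",
              length(x$barcodes), length(x$positions),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.mt_tensor <- function(x) c(length(x$barcodes), length(x$positions))

#' Per-cell coverage at each stored position
#'
#' Coverage is the sum of reads over all four bases and both strands.
#'
#' @param tensor an [mt_tensor()].
#' @return numeric matrix, cells x positions.
#' @export
tensor_coverage <- function(tensor) {
  cov <- apply(tensor$counts, c(1, 2), sum)
  dimnames(cov) <- list(tensor$barcodes, as.character(tensor$positions))
  cov
}

# Parse variant ids of the form "<pos><REF>><ALT>", e.g. "7161G>A".
parse_variant_id <- function(ids) {
  m <- regmatches(ids, regexec("^([0-9]+)([ACGT])>([ACGT])$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed variant id(s): ", paste(ids[bad], collapse = ", "))
  }
  data.frame(
    id = ids,
    pos = as.integer(vapply(m, `[`, "", 2L)),
    ref = vapply(m, `[`, "", 3L),
    alt = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

format_variant_id <- function(pos, ref, alt) paste0(pos, ref, ">", alt)

# Alternate-allele read counts for one variant: cells x strands matrix.
variant_alt_counts <- function(tensor, pos, alt) {
  j <- match(pos, tensor$positions)
  if (is.na(j)) stop("position ", pos, " not present in tensor")
  tensor$counts[, j, alt, , drop = TRUE]
}

# Resolve variant ids against the tensor, validating REF/ALT.
resolve_variants <- function(tensor, variant_ids) {
  v <- parse_variant_id(variant_ids)
  j <- match(v$pos, tensor$positions)
  if (anyNA(j)) {
    stop("variant position(s) not in tensor: ",
         paste(v$id[is.na(j)], collapse = ", "))
  }
  ref_at <- tensor$ref[j]
  if (any(v$ref != ref_at)) {
    stop("REF mismatch for: ", paste(v$id[v$ref != ref_at], collapse = ", "))
  }
  if (any(v$alt == v$ref)) {
    stop("ALT equals reference base for: ",
         paste(v$id[v$alt == v$ref], collapse = ", "))
  }
  v$col <- j
  v
}
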