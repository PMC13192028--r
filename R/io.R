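#' Write per-base strand count CSVs
#'
#' Serializes an [mt_tensor()] to the on-disk dialect of single-cell mtDNA
#' genotyping pipelines: one CSV per base (`A.csv`, `C.csv`, `G.csv`,
#' `T.csv`; columns `position`, `barcode`, `plus`, `minus`, nonzero rows
#' only), `barcodes.tsv`, and `refallele.tsv` (`position`, `ref`). mtDNA
#' positions are 1-based inclusive.
#'
#' @param tensor an [mt_tensor()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_base_counts <- function(tensor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in BASES) {
    plus <- tensor$counts[, , b, 1L, drop = FALSE][, , 1, 1]
    minus <- tensor$counts[, , b, 2L, drop = FALSE][, , 1, 1]
    plus <- matrix(plus, length(tensor$barcodes))
    minus <- matrix(minus, length(tensor$barcodes))
    nz <- which(plus + minus > 0, arr.ind = TRUE)
    df <- data.frame(position = tensor$positions[nz[, 2]],
                     barcode = tensor$barcodes[nz[, 1]],
                     plus = plus[nz], minus = minus[nz])
    df <- df[order(df$position, df$barcode), , drop = FALSE]
    write.table(df, file.path(dir, paste0(b, ".csv")), sep = ",",
                row.names = FALSE, quote = FALSE)
  }
  writeLines(tensor$barcodes, file.path(dir, "barcodes.tsv"))
  write.table(data.frame(position = tensor$positions, ref = tensor$ref),
              file.path(dir, "refallele.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read per-base strand count CSVs
#'
#' Inverse of [write_base_counts()]. Validates that all four base files are
#' present, barcodes are unique and consistent, and positions are within
#' the mitochondrial genome; malformed rows are reported with file and line.
#'
#' @param dir directory holding `A.csv` .. `T.csv`, `barcodes.tsv`,
#'   `refallele.tsv`.
#' @return an [mt_tensor()].
#' @export
read_base_counts <- function(dir) {
  bc_file <- file.path(dir, "barcodes.tsv")
  ref_file <- file.path(dir, "refallele.tsv")
  for (f in c(bc_file, ref_file, file.path(dir, paste0(BASES, ".csv")))) {
    if (!file.exists(f)) stop("missing file: ", f)
  }
  barcodes <- readLines(bc_file)
  if (anyDuplicated(barcodes)) {
    stop("duplicated barcode(s) in ", bc_file, ": ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  }
  ref <- read.table(ref_file, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character"))
  if (any(ref$position < 1 | ref$position > MT_GENOME_LENGTH)) {
    stop("position out of range in ", ref_file)
  }
  positions <- ref$position
  counts <- array(0L, dim = c(length(barcodes), length(positions), 4L, 2L))
  for (b in BASES) {
    f <- file.path(dir, paste0(b, ".csv"))
    raw <- readLines(f)
    if (length(raw) < 1L) stop("empty file: ", f)
    fields <- strsplit(raw[-1], ",", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 4L)) {
      stop("malformed line ", which(nf != 4L)[1] + 1L, " in ", f)
    }
    if (length(fields)) {
      m <- do.call(rbind, fields)
      pos <- as.integer(m[, 1])
      j <- match(pos, positions)
      i <- match(m[, 2], barcodes)
      if (anyNA(j)) stop("position out of range at line ",
                         which(is.na(j))[1] + 1L, " in ", f)
      if (anyNA(i)) stop("unknown barcode at line ",
                         which(is.na(i))[1] + 1L, " in ", f)
      bi <- match(b, BASES)
      counts[cbind(i, j, bi, 1L)] <- as.integer(m[, 3])
      counts[cbind(i, j, bi, 2L)] <- as.integer(m[, 4])
    }
  }
  mt_tensor(counts, barcodes, positions, ref$ref)
}

#' Write a heteroplasmy matrix as sparse MTX with a missing-mask sidecar
#'
#' Zero and missing are semantically different (a true 0 is evidence of
#' absence; `NA` is no evidence), so the values matrix and a mask of missing
#' entries are stored as two MTX files, with rows (cells) and columns
#' (variants) as TSV sidecars.
#'
#' @param het heteroplasmy matrix (cells x variants, `NA` = missing).
#' @param prefix path prefix; writes `<prefix>.mtx`, `<prefix>.missing.mtx`,
#'   `<prefix>.rows.tsv`, `<prefix>.cols.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_het_matrix <- function(het, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  vals <- het
  vals[is.na(vals)] <- 0
  Matrix::writeMM(methods::as(Matrix::Matrix(vals, sparse = TRUE),
                              "generalMatrix"),
                  paste0(prefix, ".mtx"))
  mask <- Matrix::Matrix(is.na(het) * 1, sparse = TRUE)
  Matrix::writeMM(methods::as(mask, "generalMatrix"),
                  paste0(prefix, ".missing.mtx"))
  writeLines(rownames(het), paste0(prefix, ".rows.tsv"))
  writeLines(colnames(het), paste0(prefix, ".cols.tsv"))
  invisible(prefix)
}

#' Read a heteroplasmy matrix written by [write_het_matrix()]
#'
#' @param prefix path prefix used when writing.
#' @return heteroplasmy matrix with `NA` for missing entries.
#' @export
read_het_matrix <- function(prefix) {
  vals <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  mask <- as.matrix(Matrix::readMM(paste0(prefix, ".missing.mtx")))
  vals[mask > 0] <- NA_real_
  rownames(vals) <- readLines(paste0(prefix, ".rows.tsv"))
  colnames(vals) <- readLines(paste0(prefix, ".cols.tsv"))
  vals
}

#' Write / read a 10x-style fragments file
#'
#' Tab-separated `chrom`, `start`, `end`, `barcode`, `count`; 0-based
#' half-open coordinates, no header.
#'
#' @param fragments BED-like data.frame.
#' @param path output path.
#' @return `path` invisibly / the data.frame.
#' @export
write_fragments <- function(fragments, path) {
  write.table(fragments[, c("chrom", "start", "end", "barcode", "count")],
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  df <- read.table(path, sep = "\t",
                   col.names = c("chrom", "start", "end", "barcode", "count"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character", "integer"))
  df
}

#' Write / read an AIRR-style clonotype table
#'
#' Tab-separated with header: `cell_id`, `clone_id`, `junction_aa`.
#'
#' @param bcr data.frame with those columns.
#' @param path output path.
#' @return `path` invisibly / the data.frame.
#' @export
write_airr <- function(bcr, path) {
  write.table(bcr[, c("cell_id", "clone_id", "junction_aa")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_airr
#' @export
read_airr <- function(path) {
  read.table(path, sep = "\t", header = TRUE,
             colClasses = "character")
}

#' Write / read a chrom.sizes file
#'
#' @param genome named numeric vector of contig sizes.
#' @param path output path.
#' @return `path` invisibly / a named numeric vector.
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(data.frame(chrom = names(genome), size = unname(genome)),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t",
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  setNames(df$size, df$chrom)
}

#' Serialize / restore a simulation config as YAML
#'
#' Round-trips losslessly: `read_sim_config(write_sim_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config a [sim_config()].
#' @param path output path.
#' @return `path` invisibly / a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$genome <- as.list(x$genome)
  if (!is.null(x$planted_cnvs)) {
    x$planted_cnvs <- lapply(seq_len(nrow(x$planted_cnvs)), function(i) {
      as.list(x$planted_cnvs[i, , drop = FALSE])
    })
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$genome <- unlist(x$genome)
  if (!is.null(x$planted_cnvs)) {
    x$planted_cnvs <- do.call(rbind, lapply(x$planted_cnvs, as.data.frame))
  }
  if (!is.null(x$positions)) x$positions <- lapply(x$positions, as.integer)
  if (length(x$injected_shifts) == 0) x$injected_shifts <- list()
  do.call(sim_config, x)
}

#' Validate a sample sheet
#'
#' A sample sheet lists one row per sample with its identifiers and file
#' locations: `sample_id`, `donor`, `timepoint`, `compartment`, and path
#' columns (`counts_dir`, `fragments`, `bcr`; `NA` allowed where a modality
#' is absent). Ids must be unique and every non-`NA` path must exist.
#'
#' @param sheet data.frame.
#' @return `sheet`, invisibly, or an error describing the violation.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "donor", "timepoint", "compartment")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id")
  for (col in intersect(c("counts_dir", "fragments", "bcr"), names(sheet))) {
    p <- sheet[[col]]
    bad <- !is.na(p) & !file.exists(p)
    if (any(bad)) stop("missing path(s) in ", col, ": ",
                       paste(p[bad], collapse = ", "))
  }
  invisible(sheet)
}
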