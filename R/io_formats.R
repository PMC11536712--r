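# Readers, writers, variant/BCR-position filters and data-derived
# hyperparameters.  Count matrices are accepted in MatrixMarket triplet
# convention (variants x cells, 1-based on disk) or as dense TSV; internally
# everything is a base dense matrix with variant/cell labels.

#' Variant read data container
#'
#' Holds the alternate (`A`) and total (`D`) UMI count matrices over N SNV
#' positions by M cells, together with variant ids and cell barcodes.
#'
#' @param alt_counts,total_counts nonnegative integer N x M matrices with
#'   `alt_counts <= total_counts` elementwise
#' @param variant_ids length-N character labels (e.g. `chrom:pos:ref:alt`)
#' @param cell_barcodes length-M character labels
#' @return an object of class `variant_read_data`
#' @export
variant_read_data <- function(alt_counts, total_counts, variant_ids,
                              cell_barcodes) {
  alt_counts <- as.matrix(alt_counts)
  total_counts <- as.matrix(total_counts)
  if (!identical(dim(alt_counts), dim(total_counts)))
    stop("alternate and total count matrices must have identical dimensions")
  if (length(variant_ids) != nrow(alt_counts))
    stop("variant_ids length does not match the number of matrix rows")
  if (length(cell_barcodes) != ncol(alt_counts))
    stop("cell_barcodes length does not match the number of matrix columns")
  if (any(alt_counts < 0) || any(total_counts < 0))
    stop("negative counts are not allowed")
  bad <- which(alt_counts > total_counts, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "alternate count exceeds total count for variant '%s' in cell '%s'",
      variant_ids[bad[1, 1]], cell_barcodes[bad[1, 2]]))
  }
  dimnames(alt_counts) <- dimnames(total_counts) <-
    list(variant_ids, cell_barcodes)
  structure(
    list(alt = alt_counts, total = total_counts,
         variant_ids = as.character(variant_ids),
         cell_barcodes = as.character(cell_barcodes)),
    class = "variant_read_data")
}

#' @exportS3Method base::print
print.variant_read_data <- function(x, ...) {
  cat(sprintf("variant_read_data: %d variants x %d cells (%d alt UMIs, %d total UMIs)\n",
              nrow(x$alt), ncol(x$alt), sum(x$alt), sum(x$total)))
  invisible(x)
}

read_count_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "%%MatrixMarket")) {
    m <- Matrix::readMM(path)
    if (methods::is(m, "TsparseMatrix")) {
      key <- paste(m@i, m@j)
      if (anyDuplicated(key)) {
        warning("duplicate (row, column) entries in '", path,
                "' were summed", call. = FALSE)
      }
    }
    res <- as.matrix(as(m, "CsparseMatrix"))
    storage.mode(res) <- "double"
    res
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
}

#' Read alternate/total UMI count matrices
#'
#' Accepts MatrixMarket triplet files (variants x cells; duplicate entries
#' are summed with a warning) or dense numeric TSV without headers, plus
#' one-label-per-line variant and barcode files.
#'
#' @param alt_path,total_path paths to the alternate / total count matrices
#' @param variants_path path to the variant id file (one id per line)
#' @param barcodes_path path to the cell barcode file (one barcode per line)
#' @return a [variant_read_data()] object
#' @export
read_counts <- function(alt_path, total_path, variants_path, barcodes_path) {
  for (p in c(alt_path, total_path, variants_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  alt <- read_count_matrix(alt_path)
  total <- read_count_matrix(total_path)
  variants <- trimws(readLines(variants_path))
  variants <- variants[nzchar(variants)]
  barcodes <- trimws(readLines(barcodes_path))
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(alt) != length(variants) || ncol(alt) != length(barcodes))
    stop(sprintf(
      "count matrix is %d x %d but %d variant ids and %d barcodes were supplied",
      nrow(alt), ncol(alt), length(variants), length(barcodes)))
  variant_read_data(alt, total, variants, barcodes)
}

#' Write count matrices in MatrixMarket form
#'
#' @param reads a [variant_read_data()] object
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_counts <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("alt.mtx", "total.mtx", "variants.txt",
                            "barcodes.txt"))
  # force general numeric sparse form so 0/1 and symmetric matrices do not
  # get written in pattern/symmetric MatrixMarket dialects
  to_dgc <- function(x) {
    m <- Matrix::Matrix(x, sparse = TRUE)
    as(as(as(m, "generalMatrix"), "dMatrix"), "CsparseMatrix")
  }
  Matrix::writeMM(to_dgc(reads$alt), paths[1])
  Matrix::writeMM(to_dgc(reads$total), paths[2])
  writeLines(reads$variant_ids, paths[3])
  writeLines(reads$cell_barcodes, paths[4])
  invisible(paths)
}

#' Read per-cell BCR chain sequences
#'
#' Reads a delimited table with barcode, heavy-chain and light-chain columns
#' and returns per-cell concatenated heavy+light sequences.  Cells missing
#' either chain are dropped (and counted); any character other than A/C/G/T
#' or the declared missing symbol is an error.  A FASTA file of
#' pre-concatenated sequences keyed by barcode is also accepted (requires
#' the Biostrings package).
#'
#' @param path CSV/TSV file (or `.fa`/`.fasta`)
#' @param barcode_col,heavy_col,light_col column names in the delimited file
#' @param missing_char symbol for a missing nucleotide (default `"N"`)
#' @return object of class `bcr_sequences`: barcodes, concatenated
#'   sequences, and the number of dropped cells
#' @export
read_bcr <- function(path, barcode_col = "barcode", heavy_col = "heavy_seq",
                     light_col = "light_seq", missing_char = "N") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA BCR input requires the Biostrings package")
    ss <- Biostrings::readDNAStringSet(path)
    seqs <- toupper(as.character(ss))
    return(bcr_sequences(names(ss), seqs, n_dropped = 0L,
                         missing_char = missing_char))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  for (col in c(barcode_col, heavy_col, light_col))
    if (!col %in% names(tab)) stop("missing column '", col, "' in ", path)
  heavy <- toupper(trimws(as.character(tab[[heavy_col]])))
  light <- toupper(trimws(as.character(tab[[light_col]])))
  complete <- !is.na(heavy) & !is.na(light) & nzchar(heavy) & nzchar(light)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(n_dropped, " cell(s) without complete heavy and light chains dropped")
  bcr_sequences(as.character(tab[[barcode_col]])[complete],
                paste0(heavy[complete], light[complete]),
                n_dropped = n_dropped, missing_char = missing_char)
}

#' @rdname read_bcr
#' @param barcodes,sequences vectors defining the object directly
#' @param n_dropped number of cells dropped for incomplete chains
#' @export
bcr_sequences <- function(barcodes, sequences, n_dropped = 0L,
                          missing_char = "N") {
  sequences <- toupper(sequences)
  chars <- unique(unlist(strsplit(sequences, "", fixed = TRUE)))
  bad <- setdiff(chars, c(NUCLEOTIDES, missing_char))
  if (length(bad) > 0)
    stop("invalid nucleotide symbol(s) in BCR sequences: ",
         paste(bad, collapse = ", "))
  structure(list(barcodes = as.character(barcodes), sequences = sequences,
                 n_dropped = as.integer(n_dropped),
                 missing_char = missing_char),
            class = "bcr_sequences")
}

#' BCR alignment container
#'
#' An M x L matrix of nucleotides at the retained variable BCR positions.
#'
#' @param nucleotides character M x L matrix over A/C/G/T plus the missing
#'   symbol
#' @param position_ids length-L position labels
#' @param cell_barcodes length-M cell barcodes
#' @param missing_char missing-nucleotide symbol
#' @return object of class `bcr_alignment`
#' @export
bcr_alignment <- function(nucleotides, position_ids, cell_barcodes,
                          missing_char = "N") {
  nucleotides <- as.matrix(nucleotides)
  if (length(position_ids) != ncol(nucleotides))
    stop("position_ids length does not match alignment columns")
  if (length(cell_barcodes) != nrow(nucleotides))
    stop("cell_barcodes length does not match alignment rows")
  encode_nucleotides(nucleotides, missing_char)  # validates the alphabet
  dimnames(nucleotides) <- list(cell_barcodes, position_ids)
  structure(list(nucleotides = nucleotides,
                 position_ids = as.character(position_ids),
                 cell_barcodes = as.character(cell_barcodes),
                 missing_char = missing_char),
            class = "bcr_alignment")
}

#' @exportS3Method base::print
print.bcr_alignment <- function(x, ...) {
  cat(sprintf("bcr_alignment: %d cells x %d variable positions\n",
              nrow(x$nucleotides), ncol(x$nucleotides)))
  invisible(x)
}

#' Consensus nucleotide of each alignment column
#'
#' Majority nucleotide among non-missing entries; ties broken in fixed
#' A < C < G < T order.  Columns with no observed nucleotide give `NA`.
#' @param mat character matrix of nucleotides
#' @param missing_char missing symbol
#' @return character vector of length `ncol(mat)`
#' @keywords internal
column_consensus <- function(mat, missing_char = "N") {
  apply(mat, 2, function(col) {
    counts <- tabulate(match(col, NUCLEOTIDES), nbins = 4L)
    if (sum(counts) == 0L) NA_character_ else NUCLEOTIDES[which.max(counts)]
  })
}

#' Select variable BCR positions
#'
#' Keeps exactly the columns in which at least one cell carries a
#' non-missing nucleotide different from the column consensus (majority
#' vote, ties broken A < C < G < T).  The reference against which
#' "alternate" is defined is therefore the per-position consensus of the
#' supplied cells; the consensus used is recorded in the result.
#'
#' @param seqs a `bcr_sequences` object (equal-length, pre-aligned
#'   sequences)
#' @return a [bcr_alignment()] over the variable positions, with attributes
#'   `consensus` (per kept position) and `kept_positions` (1-based indices
#'   into the input sequence)
#' @export
select_bcr_positions <- function(seqs) {
  stopifnot(inherits(seqs, "bcr_sequences"))
  lens <- nchar(seqs$sequences)
  if (length(unique(lens)) > 1)
    stop("BCR sequences must be pre-aligned to equal length; got lengths ",
         paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, strsplit(seqs$sequences, "", fixed = TRUE))
  cons <- column_consensus(mat, seqs$missing_char)
  observed <- mat != seqs$missing_char
  variable <- vapply(seq_len(ncol(mat)), function(l) {
    !is.na(cons[l]) && any(observed[, l] & mat[, l] != cons[l])
  }, logical(1))
  if (!any(variable))
    stop("no variable BCR positions found: the BCR sequences carry no ",
         "information for hyperclustering")
  keep <- which(variable)
  out <- bcr_alignment(mat[, keep, drop = FALSE],
                       position_ids = paste0("pos_", keep),
                       cell_barcodes = seqs$barcodes,
                       missing_char = seqs$missing_char)
  attr(out, "consensus") <- cons[keep]
  attr(out, "kept_positions") <- keep
  out
}

#' Write / read a BCR alignment as TSV
#'
#' One row per cell: barcode followed by one nucleotide column per retained
#' position (header row holds the position ids).
#' @param bcr a [bcr_alignment()]
#' @param path output path
#' @export
write_bcr_alignment <- function(bcr, path) {
  df <- data.frame(barcode = bcr$cell_barcodes, bcr$nucleotides,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bcr_alignment
#' @param missing_char missing-nucleotide symbol
#' @export
read_bcr_alignment <- function(path, missing_char = "N") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  bcr_alignment(as.matrix(df[, -1, drop = FALSE]),
                position_ids = colnames(df)[-1],
                cell_barcodes = df[[1]], missing_char = missing_char)
}

#' Write / read a binary clone genotype matrix as TSV
#'
#' Rows are variant ids, columns clone ids, entries 0/1.
#' @param geno binary N x K matrix with dimnames
#' @param path file path
#' @export
write_genotypes <- function(geno, path) {
  utils::write.table(geno, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!all(m %in% c(0, 1)))
    stop("genotype matrix entries must be 0/1")
  storage.mode(m) <- "integer"
  m
}

#' Filter variants for modelling
#'
#' Keeps variants that are SNVs, are either somatic-called or show more than
#' a 3-fold increase of the alternate-allele frequency in tumour over normal
#' (germline-leak rule), and have at least one alternate read across the
#' cells.
#'
#' @param table data frame with columns `id`, `tumour_vaf`, `normal_vaf`,
#'   `is_snv`, `somatic_call`; its ids must cover the read matrix ids
#' @param reads a [variant_read_data()]
#' @return list with elements `reads` (filtered) and `kept_ids`
#' @export
filter_variants <- function(table, reads) {
  req <- c("id", "tumour_vaf", "normal_vaf", "is_snv", "somatic_call")
  if (!all(req %in% names(table)))
    stop("variant table must have columns: ", paste(req, collapse = ", "))
  if (any(table$tumour_vaf < 0 | table$tumour_vaf > 1) ||
      any(table$normal_vaf < 0 | table$normal_vaf > 1))
    stop("VAFs must lie in [0, 1]")
  idx <- match(reads$variant_ids, table$id)
  if (anyNA(idx))
    stop("variant table is missing ids present in the count matrices: ",
         paste(utils::head(reads$variant_ids[is.na(idx)], 5), collapse = ", "))
  tab <- table[idx, ]
  keep <- tab$is_snv &
    (tab$somatic_call | tab$tumour_vaf > 3 * tab$normal_vaf) &
    rowSums(reads$alt) >= 1
  if (!any(keep)) {
    warning("no variants passed the filters", call. = FALSE)
    keep_idx <- integer(0)
  } else {
    keep_idx <- which(keep)
  }
  out <- variant_read_data(reads$alt[keep_idx, , drop = FALSE],
                           reads$total[keep_idx, , drop = FALSE],
                           reads$variant_ids[keep_idx],
                           reads$cell_barcodes)
  list(reads = out, kept_ids = reads$variant_ids[keep_idx])
}

#' Derive data-dependent prior hyperparameters
#'
#' The read-error probability prior (theta0) is centred at 0.002 with
#' strength equal to the total number of reference reads; each carrier
#' probability prior (theta_i) is centred at 0.45 with strength equal to the
#' total alternate reads of that variant (floored at `min_nu_magnitude` when
#' a variant has no alternate reads); the genotype error rate prior (xi) is
#' centred at 0.8 agreement weight with strength N*K; the BCR profile prior
#' is the flat low-strength g = (0.01, 0.01, 0.01, 0.01) at every position;
#' the CRP concentration prior is Gamma(1, 1).
#'
#' @param reads a [variant_read_data()] (nonempty)
#' @param n_clones number of clones K
#' @param n_bcr_positions number of variable BCR positions L
#' @param min_nu_magnitude floor on the theta_i prior strength
#' @return object of class `bcr_hyperparams`: `kappa` (length 2), `nu0`
#'   (length 2), `nu_i` (N x 2), `g` (L x 4), `alpha0_prior` (length 2)
#' @export
derive_hyperparams <- function(reads, n_clones, n_bcr_positions,
                               min_nu_magnitude = 10) {
  if (nrow(reads$alt) == 0) stop("no variants in the read data")
  total_ref <- sum(reads$total - reads$alt)
  mag0 <- max(total_ref, min_nu_magnitude)
  nu0 <- c(0.002 * mag0, 0.998 * mag0)
  alt_i <- rowSums(reads$alt)
  mag_i <- ifelse(alt_i > 0, alt_i, min_nu_magnitude)
  nu_i <- cbind(0.45 * mag_i, 0.55 * mag_i)
  nk <- nrow(reads$alt) * n_clones
  hyperparams(kappa = c(0.8 * nk, 0.2 * nk), nu0 = nu0, nu_i = nu_i,
              g = matrix(0.01, n_bcr_positions, 4),
              alpha0_prior = c(1, 1))
}

#' Construct a hyperparameter set directly
#'
#' @param kappa Beta prior (error weight, agreement weight) on the genotype
#'   error rate xi
#' @param nu0 Beta prior on theta0
#' @param nu_i N x 2 matrix of Beta priors on each theta_i (a length-2
#'   vector is recycled across variants via [expand_nu_i()])
#' @param g L x 4 Dirichlet prior on the BCR profiles (a scalar or length-4
#'   vector is expanded)
#' @param alpha0_prior Gamma(shape, rate) prior on the CRP concentration
#' @export
hyperparams <- function(kappa, nu0, nu_i, g, alpha0_prior = c(1, 1)) {
  nu_i <- as.matrix(nu_i)
  if (ncol(nu_i) != 2) stop("nu_i must have two columns")
  g <- as.matrix(g)
  vals <- c(kappa, nu0, nu_i, g, alpha0_prior)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hyperparameters must be strictly positive and finite")
  structure(list(kappa = kappa, nu0 = nu0, nu_i = nu_i, g = g,
                 alpha0_prior = alpha0_prior),
            class = "bcr_hyperparams")
}

#' Expand shorthand hyperparameter forms to full shape
#' @param nu_i length-2 vector or N x 2 matrix
#' @param n_variants N
#' @return N x 2 matrix
#' @export
expand_nu_i <- function(nu_i, n_variants) {
  if (is.matrix(nu_i)) {
    if (nrow(nu_i) == n_variants) return(nu_i)
    if (nrow(nu_i) == 1) return(nu_i[rep(1, n_variants), , drop = FALSE])
    stop("nu_i has ", nrow(nu_i), " rows but there are ", n_variants,
         " variants")
  }
  matrix(nu_i, n_variants, 2, byrow = TRUE)
}

#' @rdname expand_nu_i
#' @param g scalar, length-4 vector, or L x 4 matrix
#' @param n_positions L
#' @export
expand_g <- function(g, n_positions) {
  if (is.matrix(g)) {
    if (nrow(g) == n_positions && ncol(g) == 4) return(g)
    stop("g must be an L x 4 matrix")
  }
  if (length(g) == 1) g <- rep(g, 4)
  if (length(g) != 4) stop("g must be a scalar, length-4 vector or L x 4 matrix")
  matrix(g, n_positions, 4, byrow = TRUE)
}
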