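#' Read a genetic map from CSV
#'
#' Expects a comma-separated file with header columns \code{marker},
#' \code{chromosome}, \code{position_cM}. Markers must be sorted by
#' nondecreasing position within each chromosome; violations are rejected
#' with the offending marker named.
#'
#' @param path path to the CSV file.
#' @return a \linkS4class{GeneticMap}.
#' @export
readGeneticMap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(df)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  pos <- suppressWarnings(as.numeric(df$position_cM))
  if (anyNA(pos))
    stop("non-numeric position for marker ",
         df$marker[which(is.na(pos))[1]])
  geneticMap(as.character(df$marker), as.character(df$chromosome), pos)
}

#' Construct a GeneticMap
#'
#' @param marker,chromosome,position parallel vectors of marker id,
#'   chromosome label and position in cM.
#' @return a \linkS4class{GeneticMap}.
#' @export
geneticMap <- function(marker, chromosome, position) {
  new("GeneticMap", marker = as.character(marker),
      chromosome = as.character(chromosome),
      position = as.numeric(position))
}

#' Read a genotype matrix from CSV
#'
#' Individuals x markers table with marker names in the header; an
#' optional first column \code{id} supplies individual labels. Entries are
#' either the labels \code{AA}/\code{aa} or the numeric codes
#' \code{0.5}/\code{-0.5}. Heterozygote or unknown classes and missing
#' cells are errors: the coding targets fully inbred RILs.
#'
#' @param path path to the CSV file.
#' @param map a \linkS4class{GeneticMap}; columns are reordered to map
#'   order and must match its markers exactly.
#' @return numeric matrix N x L coded +0.5/-0.5 with marker colnames.
#' @export
readGenotypes <- function(path, map) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] == "id") {
    ids <- as.character(df[[1]]); df <- df[-1]
  } else ids <- NULL
  if (!setequal(names(df), map@marker))
    stop("genotype columns do not match map markers")
  df <- df[map@marker]
  g <- as.matrix(df)
  if (is.character(g)) {
    bad <- setdiff(unique(as.vector(g)), c("AA", "aa"))
    if (length(bad))
      stop("unsupported genotype class: ", bad[1],
           " (only AA/aa are allowed for RILs)")
    g <- matrix(ifelse(g == "AA", 0.5, -0.5), nrow(df), ncol(df))
  } else {
    g <- matrix(as.numeric(g), nrow(df), ncol(df))
    if (anyNA(g)) stop("missing genotype values are not supported")
    if (!all(g == 0.5 | g == -0.5))
      stop("numeric genotypes must be coded 0.5/-0.5")
  }
  dimnames(g) <- list(ids, map@marker)
  g
}

#' Read a phenotype matrix from CSV
#'
#' Rectangular numeric table with trait names in the header; an optional
#' first column \code{id} supplies individual labels. Missing cells are an
#' error (no imputation).
#'
#' @param path path to the CSV file.
#' @return numeric matrix N x p with trait colnames.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] == "id") {
    ids <- as.character(df[[1]]); df <- df[-1]
  } else ids <- NULL
  y <- as.matrix(df)
  storage.mode(y) <- "double"
  if (anyNA(y)) stop("missing phenotype values are not supported")
  dimnames(y) <- list(ids, names(df))
  y
}

#' Assemble a QTLCross from genotypes, phenotypes and a map
#'
#' Validates alignment of the three components; misalignment is an error,
#' never a silent reordering.
#'
#' @param genotypes numeric N x L matrix coded +0.5/-0.5 (colnames, if
#'   present, must already be in map order).
#' @param phenotypes numeric N x p matrix.
#' @param map a \linkS4class{GeneticMap}.
#' @return a \linkS4class{QTLCross}.
#' @export
qtlCross <- function(genotypes, phenotypes, map) {
  if (!is.null(rownames(genotypes)) && !is.null(rownames(phenotypes)) &&
      !identical(rownames(genotypes), rownames(phenotypes)))
    stop("genotype and phenotype individuals are not aligned")
  new("QTLCross", genotypes = genotypes,
      phenotypes = as.matrix(phenotypes), map = map)
}

#' Read map, genotype and phenotype CSV files into a QTLCross
#'
#' @param mapPath,genoPath,phenoPath paths to the three CSV files.
#' @return a \linkS4class{QTLCross}.
#' @export
readCross <- function(mapPath, genoPath, phenoPath) {
  map <- readGeneticMap(mapPath)
  qtlCross(readGenotypes(genoPath, map), readPhenotypes(phenoPath), map)
}

#' Write cross components to CSV
#'
#' Inverse of the readers: \code{writeGeneticMap} emits
#' marker/chromosome/position_cM, the matrix writers emit an \code{id}
#' column followed by marker or trait columns. Numeric values round-trip
#' bit-exactly through \code{\link{readCross}}.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGeneticMap <- function(map, path) {
  df <- data.frame(marker = map@marker, chromosome = map@chromosome,
                   position_cM = .fmt(map@position))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 17 significant digits: doubles survive the text round trip bit-exactly
.fmt <- function(x) sprintf("%.17g", x)

#' @rdname writeGeneticMap
#' @param m numeric matrix (genotypes or phenotypes) with column names.
#' @export
writeMatrixCSV <- function(m, path) {
  ids <- rownames(m)
  if (is.null(ids)) ids <- seq_len(nrow(m))
  fm <- apply(m, 2L, .fmt)
  if (!is.matrix(fm)) fm <- matrix(fm, nrow(m), ncol(m))
  colnames(fm) <- colnames(m)
  df <- data.frame(id = ids, fm, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
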