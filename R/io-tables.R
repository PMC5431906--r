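## TSV interchange for the tabular evidence formats. All writers emit
## tab-separated files with a header and no quoting/row names; readers
## restore the documented column types so write -> read is the identity.

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write evidence tables as TSV
#'
#' Interchange I/O for the package's tabular formats: splice-junction
#' counts (chrom, strand, donor, acceptor, sample, count), per-region
#' coverage (gene_id, region_start, region_end, sample, mean_depth),
#' event-level PSI counts (event_id, dose, k_inc, k_exc), long reads
#' (read_id, chrom, strand, junctions, aligned_proportion, identity,
#' source) and siRNA count matrices (cg_id, library, is_control, count
#' in long form). Writing then reading reproduces the input exactly.
#'
#' @param x the table to write (for `writeSirnaTable`, the list returned
#'   by [simulateSirnaCounts()])
#' @param path file path
#' @return readers return the table; writers return `path` invisibly
#' @name table-io
NULL

#' @rdname table-io
#' @export
writeJunctionTable <- function(x, path) .writeTsv(x, path)

#' @rdname table-io
#' @export
readJunctionTable <- function(path) {
    df <- read.delim(path, colClasses = c("character", "character",
                                          "integer", "integer",
                                          "character", "integer"))
    names(df) <- c("chrom", "strand", "donor", "acceptor", "sample", "count")
    df
}

#' @rdname table-io
#' @export
writeCoverageTable <- function(x, path) .writeTsv(x, path)

#' @rdname table-io
#' @export
readCoverageTable <- function(path) {
    df <- read.delim(path, colClasses = c("character", "integer", "integer",
                                          "character", "numeric"))
    names(df) <- c("gene_id", "region_start", "region_end", "sample",
                   "mean_depth")
    df
}

#' @rdname table-io
#' @export
writeEventCountTable <- function(x, path) .writeTsv(x, path)

#' @rdname table-io
#' @export
readEventCountTable <- function(path) {
    df <- read.delim(path, colClasses = c("character", "character",
                                          "integer", "integer"))
    names(df) <- c("event_id", "dose", "k_inc", "k_exc")
    df
}

#' @rdname table-io
#' @export
writeLongReadTable <- function(x, path) .writeTsv(x, path)

#' @rdname table-io
#' @export
readLongReadTable <- function(path) {
    df <- read.delim(path, colClasses = c("character", "character",
                                          "character", "character",
                                          "numeric", "numeric", "character"))
    names(df) <- c("read_id", "chrom", "strand", "junctions",
                   "aligned_proportion", "identity", "source")
    df
}

#' @rdname table-io
#' @export
writeSirnaTable <- function(x, path) {
    long <- data.frame(
        cg_id = rep(rownames(x$counts), times = ncol(x$counts)),
        library = rep(colnames(x$counts), each = nrow(x$counts)),
        is_control = rep(unname(x$isControl), each = nrow(x$counts)),
        count = as.vector(x$counts), stringsAsFactors = FALSE)
    .writeTsv(long, path)
}

#' @rdname table-io
#' @export
readSirnaTable <- function(path) {
    df <- read.delim(path, colClasses = c("character", "character",
                                          "logical", "numeric"))
    ids <- unique(df$cg_id); libs <- unique(df$library)
    counts <- matrix(NA_real_, length(ids), length(libs),
                     dimnames = list(ids, libs))
    counts[cbind(match(df$cg_id, ids), match(df$library, libs))] <- df$count
    isControl <- setNames(df$is_control[match(libs, df$library)], libs)
    list(counts = counts, isControl = isControl)
}
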