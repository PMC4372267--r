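#  Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cnd <- structure(
    class = c(class, "azadem_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cnd)
}

warn2 <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#  Equal-frequency bins 1..n_bins (ties broken by first occurrence so the
#  binning is deterministic).
ntile <- function(x, n_bins = 5L) {
  r <- rank(x, ties.method = "first", na.last = "keep")
  as.integer(ceiling(r * n_bins / sum(!is.na(x))))
}

#' Derive a per-stage seed from a global seed
#'
#' Fans one global seed out to independent per-stage seeds by adding a
#' polynomial hash of the stage name (mod 2^31 - 2), so individual stages can
#' be rerun reproducibly in isolation.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483629
  as.integer((as.numeric(seed) + h) %% 2147483629 + 1)
}

#  data.frame (0-based half-open) <-> GRanges (1-based closed)
df_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else rep(".", nrow(df))
  strand[is.na(strand) | strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

granges_to_df <- function(gr) {
  s <- as.character(BiocGenerics::strand(gr))
  s[s == "*"] <- "."
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = s,
    stringsAsFactors = FALSE
  )
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")  # LF line endings on every platform
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
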