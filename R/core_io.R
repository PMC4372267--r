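#  Genomic data model and readers/writers.
#
#  Every interval in the package is a data.frame row with columns
#  chrom / start / end / strand, 0-based half-open [start, end).  The only
#  places 1-based closed coordinates exist are the file boundaries (GTF) and
#  transient GRanges used for overlap arithmetic.

#' Construct a validated table of genomic intervals
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open, `start < end`.
#' @param strand Strand characters among `"+"`, `"-"`, `"."` (default `"."`).
#' @param ... Further equal-length columns (e.g. `name`, `score`, `summit`).
#' @return A data.frame of intervals.
#' @examples
#' genomic_intervals("chr1", 10, 20)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate the half-open interval invariants
#'
#' Checks 0-based half-open coordinates (`start >= 0`, `start < end`) and
#' legal strand codes; stops with the offending row numbers otherwise.
#'
#' @param df Interval data.frame (`chrom`, `start`, `end`, optional `strand`).
#' @param context Label used in error messages.
#' @return `df`, invisibly.
#' @export
validate_intervals <- function(df, context = "interval") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop2("%s table lacks column(s): %s", context, paste(miss, collapse = ", "))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 | df$start >= df$end)
  if (length(bad) > 0)
    stop2("%s rows violate 0-based half-open invariant (start < end, start >= 0): %s",
          context, paste(head(bad, 10), collapse = ", "),
          class = "azadem_interval_error")
  if ("strand" %in% names(df)) {
    badstr <- which(!df$strand %in% c("+", "-", "."))
    if (length(badstr) > 0)
      stop2("%s rows carry illegal strand codes: %s", context,
            paste(head(badstr, 10), collapse = ", "))
  }
  invisible(df)
}

#' Read intervals from a BED3+ file
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Columns 4-6 become `name`, `score`, `strand` when present; a 7th numeric
#' column is interpreted as a summit offset relative to `start` (narrowPeak
#' convention) and exposed as absolute `summit`.
#'
#' @param path BED file path.
#' @return Interval data.frame.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop2("no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop2("BED parse error at line %d: fewer than 3 fields",
          lineno[which(nf < 3)[1]])
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  badnum <- which(is.na(start) | is.na(end))
  if (length(badnum) > 0)
    stop2("BED parse error at line %d: non-numeric coordinates", lineno[badnum[1]])
  badord <- which(start >= end | start < 0)
  if (length(badord) > 0)
    stop2("BED record rejected at line %d: start >= end (intervals are 0-based half-open)",
          lineno[badord[1]], class = "azadem_interval_error")
  df <- data.frame(chrom = get(1), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (max(nf) >= 4) df$name <- get(4)
  if (max(nf) >= 5) df$score <- suppressWarnings(as.numeric(get(5)))
  df$strand <- if (max(nf) >= 6) {
    s <- get(6); s[is.na(s) | !s %in% c("+", "-")] <- "."; s
  } else "."
  if (max(nf) >= 7) {
    off <- suppressWarnings(as.integer(get(7)))
    if (!all(is.na(off))) df$summit <- df$start + off
  }
  validate_intervals(df, context = basename(path))
  df
}

#' Write intervals to a BED file
#'
#' Emits BED3/BED6 (+ summit offset column when `summit` is present),
#' UTF-8, LF-terminated. Round-trips losslessly through [read_intervals()].
#'
#' @param df Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(df, path) {
  validate_intervals(df, context = "write_intervals input")
  cols <- list(df$chrom, df$start, df$end)
  if (!is.null(df$summit) || !is.null(df$score) || !is.null(df$name) ||
      any(df$strand != ".")) {
    cols <- c(cols, list(df$name %||% ".",
                         df$score %||% 0,
                         df$strand %||% "."))
  }
  if (!is.null(df$summit)) cols <- c(cols, list(df$summit - df$start))
  out <- do.call(paste, c(cols, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Write a generic table as TSV (UTF-8, LF, header row)
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) write_tsv(df, path)

#' Read a TSV table written by [write_table()]
#' @param path File path.
#' @return A data.frame.
#' @export
read_table <- function(path) read_tsv(path)

#  ---- gene models -----------------------------------------------------------

#' Assemble gene models from per-gene exon tables
#'
#' Collapses exons to their union per gene (transcript isoforms are merged),
#' derives introns as the within-gene complement, and computes the TSS
#' (start on "+", end-1 on "-").
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, optional `biotype`.
#' @param exons data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param allow_unstranded Treat strand "." as "+" for TSS derivation instead
#'   of rejecting the gene (TSS-anchored analyses are strand-critical, so the
#'   default is to reject).
#' @return An object of class `gene_models`: list with data.frames `genes`
#'   (`gene_id`, `biotype`, `chrom`, `start`, `end`, `strand`, `tss`),
#'   `exons` and `introns`.
#' @export
gene_models <- function(genes, exons, allow_unstranded = FALSE) {
  if (nrow(exons) == 0) stop2("no exons supplied")
  validate_intervals(exons, context = "exon")
  missing_ex <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing_ex) > 0)
    stop2("gene(s) rejected, zero exons: %s", paste(missing_ex, collapse = ", "),
          class = "azadem_zero_exon_error")
  unstranded <- genes$gene_id[!genes$strand %in% c("+", "-")]
  if (length(unstranded) > 0) {
    if (!allow_unstranded)
      stop2(paste0("gene(s) with strand '.' rejected (TSS is strand-critical; ",
                   "set allow_unstranded = TRUE to treat '.' as '+'): %s"),
            paste(head(unstranded, 10), collapse = ", "),
            class = "azadem_strand_error")
    genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  }
  #  union of exons per gene, sorted and non-overlapping
  gr <- df_to_granges(exons)
  grl <- GenomicRanges::reduce(S4Vectors::split(gr, exons$gene_id))
  ex <- granges_to_df(unlist(grl, use.names = FALSE))
  ex$gene_id <- rep(names(grl), lengths(grl))
  ex <- ex[order(ex$gene_id, ex$start), c("gene_id", "chrom", "start", "end")]
  ids <- sort(unique(ex$gene_id))
  span <- data.frame(gene_id = ids,
                     start = as.integer(tapply(ex$start, ex$gene_id, min)[ids]),
                     end = as.integer(tapply(ex$end, ex$gene_id, max)[ids]),
                     stringsAsFactors = FALSE)
  g <- genes[match(span$gene_id, genes$gene_id), , drop = FALSE]
  gdf <- data.frame(gene_id = span$gene_id,
                    biotype = g$biotype %||% rep("coding", nrow(g)),
                    chrom = g$chrom,
                    start = as.integer(span$start),
                    end = as.integer(span$end),
                    strand = g$strand,
                    stringsAsFactors = FALSE)
  gdf$tss <- ifelse(gdf$strand == "+", gdf$start, gdf$end - 1L)
  #  introns: per-gene complement of exons within the gene span
  intr <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e) {
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = e$end[-nrow(e)], end = e$start[-1],
               stringsAsFactors = FALSE)
  }))
  if (is.null(intr))
    intr <- data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
  rownames(gdf) <- rownames(ex) <- rownames(intr) <- NULL
  structure(list(genes = gdf, exons = ex, introns = intr),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d coding, %d other), %d exons, %d introns\n",
              nrow(x$genes), sum(x$genes$biotype == "coding"),
              sum(x$genes$biotype != "coding"),
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#  Pre-scan a GTF so malformed records are reported with their line numbers
#  (rtracklayer's importer does not name lines).
prevalidate_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stop2("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
          idx[which(nf < 9)[1]], nf[which(nf < 9)[1]])
  s <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4)))
  e <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5)))
  bad <- which(is.na(s) | is.na(e) | s < 1 | s > e)
  if (length(bad) > 0)
    stop2("GTF parse error at line %d: invalid 1-based closed coordinates",
          idx[bad[1]])
  invisible(TRUE)
}

#' Read gene models from an annotation file
#'
#' GTF input (UCSC dialect, 1-based closed) is converted to the internal
#' 0-based half-open convention; BED12 blocks are expanded to exons.
#' Transcript-level annotation is collapsed to one model per `gene_id`
#' (union of exons).
#'
#' @param path Annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @param allow_unstranded Passed to [gene_models()].
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path, dialect = c("gtf", "bed12"),
                             allow_unstranded = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop2("no such file: %s", path)
  if (dialect == "gtf") {
    prevalidate_gtf(path)
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0) stop2("GTF contains no exon records: %s", path)
    exdf <- granges_to_df(ex)
    exdf$gene_id <- ex$gene_id
    genes <- unique(data.frame(gene_id = ex$gene_id,
                               chrom = exdf$chrom,
                               strand = exdf$strand,
                               biotype = if (!is.null(ex$gene_biotype))
                                 ex$gene_biotype else "coding",
                               stringsAsFactors = FALSE))
    #  genes declared by non-exon records but lacking exons -> reject by id
    declared <- unique(gr$gene_id)
    no_exon <- setdiff(declared, genes$gene_id)
    if (length(no_exon) > 0)
      stop2("gene(s) rejected, zero exons: %s", paste(no_exon, collapse = ", "),
            class = "azadem_zero_exon_error")
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    bl <- rtracklayer::blocks(gr)   # absolute 1-based exon ranges
    ex <- unlist(bl, use.names = FALSE)
    ids <- rep(gr$name, lengths(bl))
    exdf <- data.frame(chrom = rep(as.character(GenomicRanges::seqnames(gr)),
                                   lengths(bl)),
                       start = BiocGenerics::start(ex) - 1L,
                       end = BiocGenerics::end(ex),
                       gene_id = ids,
                       stringsAsFactors = FALSE)
    s <- as.character(BiocGenerics::strand(gr)); s[s == "*"] <- "."
    genes <- data.frame(gene_id = gr$name,
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        strand = s,
                        biotype = "coding",
                        stringsAsFactors = FALSE)
  }
  gene_models(genes, exdf[, c("gene_id", "chrom", "start", "end")],
              allow_unstranded = allow_unstranded)
}

#' Write gene models as a GTF file
#'
#' Internal 0-based half-open exons are converted back to 1-based closed GTF
#' records (one transcript per gene).
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  g <- models$genes
  ex <- models$exons
  m <- match(ex$gene_id, g$gene_id)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_biotype "%s";',
                   ex$gene_id, ex$gene_id, g$biotype[m])
  out <- paste(ex$chrom, "azadem", "exon", ex$start + 1L, ex$end, ".",
               g$strand[m], ".", attrs, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#  ---- tabular assay formats -------------------------------------------------

#' Read/write per-site HpaII/MspI count tables
#'
#' Columns: `chrom`, `start`, `end`, `condition`, `hpaii`, `mspi`.
#' Counts must be non-negative integers.
#'
#' @param path File path.
#' @return A data.frame (`read_site_counts`); `path` (`write_site_counts`).
#' @export
read_site_counts <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom", "start", "end", "condition", "hpaii", "mspi")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop2("site-count table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(df$hpaii < 0 | df$mspi < 0 | df$hpaii != round(df$hpaii) |
          df$mspi != round(df$mspi)))
    stop2("site counts must be non-negative integers")
  validate_intervals(df, context = "site")
  df
}

#' @rdname read_site_counts
#' @param df Site-count data.frame.
#' @export
write_site_counts <- function(df, path) write_tsv(df, path)

#' Read/write long-format expression tables
#'
#' Columns: `gene_id`, `condition`, `replicate`, `fpkm` (non-negative).
#' All conditions must share the same gene universe.
#'
#' @param path File path.
#' @return A data.frame (`read_expression`); `path` (`write_expression`).
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "condition", "replicate", "fpkm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop2("expression table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(df$fpkm < 0)) stop2("FPKM values must be >= 0")
  per_cond <- tapply(df$gene_id, df$condition, function(g) sort(unique(g)))
  if (length(per_cond) > 1 &&
      !all(vapply(per_cond, identical, TRUE, y = per_cond[[1]])))
    stop2("conditions do not share the same gene universe")
  df
}

#' @rdname read_expression
#' @param df Expression data.frame.
#' @export
write_expression <- function(df, path) write_tsv(df, path)

#' Read/write a bedGraph track
#'
#' @param path File path.
#' @return data.frame with `chrom`, `start`, `end`, `value` (`read_bedgraph`);
#'   `path` (`write_bedgraph`).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  df <- data.frame(chrom = vapply(f, `[`, "", 1),
                   start = as.integer(vapply(f, `[`, "", 2)),
                   end = as.integer(vapply(f, `[`, "", 3)),
                   value = as.numeric(vapply(f, `[`, "", 4)),
                   stringsAsFactors = FALSE)
  validate_intervals(df, context = basename(path))
  df
}

#' @rdname read_bedgraph
#' @param df bedGraph data.frame (`chrom`, `start`, `end`, `value`).
#' @export
write_bedgraph <- function(df, path) {
  out <- paste(df$chrom, df$start, df$end,
               formatC(df$value, format = "g", digits = 10), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}
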