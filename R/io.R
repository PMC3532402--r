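# Readers/writers for the standard formats the pipeline touches.  Internal
# coordinates are 0-based half-open everywhere; conversion to/from the
# 1-based inclusive GFF3 convention happens only at the GFF3 boundary.

#' Read a GFF3 gene annotation
#'
#' Imports GFF3 via `rtracklayer`, keeps `gene` features, and converts
#' coordinates to the internal 0-based half-open convention.  Features with
#' a missing or unrecognized `gene_type` attribute are assigned
#' `"other_RNA"` with a warning.
#'
#' @param path GFF3 file path.
#' @return Gene table (gene_id, chrom, start, end, strand, gene_type,
#'   te_class), sorted by chrom and start.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), gene_type = character(),
                      te_class = character(), stringsAsFactors = FALSE))
  }
  mc <- S4Vectors::mcols(gr)
  gt <- if ("gene_type" %in% names(mc)) as.character(mc$gene_type)
    else rep(NA_character_, length(gr))
  bad <- is.na(gt) | !gt %in% GENE_TYPES
  if (any(bad)) {
    warning(sum(bad), " gene(s) with missing/unknown gene_type set to ",
            "'other_RNA'", call. = FALSE)
    gt[bad] <- "other_RNA"
  }
  tc <- if ("te_class" %in% names(mc)) as.character(mc$te_class)
    else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(mc)) as.character(mc$ID)
    else sprintf("gene%05d", seq_along(gr))
  genes <- data.frame(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_type = gt, te_class = tc,
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  check_genes(genes)
}

#' Write a gene table as GFF3
#'
#' Emits one `gene` line per row with `ID`, `gene_type` and (for transposon
#' genes) `te_class` attributes; internal 0-based half-open coordinates
#' become the 1-based inclusive GFF3 convention.
#'
#' @param genes Gene table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  check_genes(genes)
  attrs <- paste0("ID=", genes$gene_id, ";gene_type=", genes$gene_type,
                  ifelse(is.na(genes$te_class), "",
                         paste0(";te_class=", genes$te_class)))
  lines <- paste(genes$chrom, "tilemark", "gene",
                 genes$start + 1L, genes$end, ".", genes$strand, ".",
                 attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write heterochromatin (or any) intervals as BED3
#' @param intervals data.frame(chrom, start, end), 0-based half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(intervals, path) {
  lines <- paste(intervals$chrom, intervals$start, intervals$end, sep = "\t")
  writeLines(c("# chrom\tstart\tend", lines), path)
  invisible(path)
}

#' Read a BED file (3+ columns, comments/track lines skipped)
#' @param path BED file path.
#' @return data.frame with chrom, start, end and, when present, name and
#'   score columns.
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^(#|track|browser)", ln) & nzchar(ln)]
  if (length(ln) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(ln, "\t", fixed = TRUE)
  nc <- min(lengths(parts))
  df <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (nc >= 4L) df$name <- vapply(parts, `[[`, "", 4L)
  if (nc >= 5L) df$score <- as.numeric(vapply(parts, `[[`, "", 5L))
  df
}

#' Write enriched regions as BED6
#'
#' Name is a sequential region id; score is `round(1000 * mean_posterior)`.
#' An empty region list yields a file holding only the header comment.
#'
#' @param regions Region table, sorted by (chrom, start).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  check_regions(regions)
  if (nrow(regions) > 1L &&
      any(unlist(tapply(regions$start, regions$chrom, is.unsorted)))) {
    tm_stop("regions must be sorted by start within each chromosome")
  }
  header <- "# chrom\tstart\tend\tname\tscore\tstrand"
  if (nrow(regions) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  score <- if ("mean_posterior" %in% names(regions)) {
    round(1000 * regions$mean_posterior)
  } else rep(0L, nrow(regions))
  lines <- paste(regions$chrom, regions$start, regions$end,
                 sprintf("region_%05d", seq_len(nrow(regions))),
                 score, ".", sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write an enrichment track as bedGraph
#'
#' Each probe point expands to `[pos, pos + span)`, clipped at the next
#' probe so intervals never overlap; values are formatted to 6 significant
#' digits.
#'
#' @param track An `"enrichment_track"`.
#' @param path Output path.
#' @param span Interval span in bp; default is the median probe spacing.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, span = NULL) {
  stopifnot(inherits(track, "enrichment_track"))
  pos <- track$positions
  if (is.unsorted(pos, strictly = TRUE)) {
    tm_stop("track positions must be strictly increasing")
  }
  if (is.null(span)) {
    span <- if (length(pos) > 1L) stats::median(diff(pos)) else 1L
  }
  ends <- pos + span
  if (length(pos) > 1L) {
    ends[-length(ends)] <- pmin(ends[-length(ends)], pos[-1])
  }
  lines <- paste(track$chrom, pos, ends,
                 formatC(track$value, format = "g", digits = 6), sep = "\t")
  writeLines(c(sprintf("track type=bedGraph name=%s", track$chrom), lines),
             path)
  invisible(path)
}

#' Write a simulated ChIP experiment as a TSV signal table
#'
#' Columns: `chrom`, `position`, then one column per channel and replicate
#' named `<mark>_<IP|input>_<rep>` (e.g. `me2_IP_1`), holding linear-scale
#' PM-MM values.
#'
#' @param experiment A `"chip_experiment"` from [generate_chip_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(experiment, path) {
  stopifnot(inherits(experiment, "chip_experiment"))
  df <- data.frame(chrom = experiment$chrom,
                   position = experiment$positions,
                   stringsAsFactors = FALSE)
  for (m in names(experiment$marks)) {
    for (ch in c("ip", "input")) {
      mat <- experiment$marks[[m]][[ch]]
      lab <- if (ch == "ip") "IP" else "input"
      for (r in seq_len(ncol(mat))) {
        df[[paste(m, lab, r, sep = "_")]] <- mat[, r]
      }
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV signal table into per-chromosome probe-track sets
#'
#' Expects the column layout written by [write_signal_table()].  Duplicate
#' probe positions on a chromosome are always an error; unsorted positions
#' are an error under `strict = TRUE` and are sorted otherwise.
#'
#' @param path TSV path.
#' @param strict Reject unsorted positions instead of sorting, default TRUE.
#' @return Named list (one element per chromosome), each a list with
#'   `chrom`, `positions`, and `marks` (per mark, `ip` and `input`
#'   matrices) - the same shape as a `"chip_experiment"`.
#' @export
read_signal_table <- function(path, strict = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("chrom", "position")
  if (!all(need %in% names(df))) {
    tm_stop("signal table must have 'chrom' and 'position' columns")
  }
  sig_cols <- setdiff(names(df), need)
  parsed <- strsplit(sig_cols, "_", fixed = TRUE)
  ok <- lengths(parsed) == 3L &
    vapply(parsed, function(p) p[2] %in% c("IP", "input"), logical(1))
  if (!all(ok)) {
    tm_stop("malformed signal column name(s): ",
            paste(sig_cols[!ok], collapse = ", "),
            " (expected <mark>_<IP|input>_<rep>)")
  }
  out <- list()
  for (chr in unique(df$chrom)) {
    sub <- df[df$chrom == chr, , drop = FALSE]
    if (anyDuplicated(sub$position)) {
      tm_stop("duplicated probe positions on ", chr)
    }
    if (is.unsorted(sub$position)) {
      if (strict) tm_stop("unsorted probe positions on ", chr,
                          " (use strict = FALSE to sort)")
      sub <- sub[order(sub$position), , drop = FALSE]
    }
    marks <- list()
    for (m in unique(vapply(parsed, `[[`, "", 1L))) {
      get_mat <- function(lab) {
        cols <- sig_cols[vapply(parsed, function(p) {
          p[1] == m && p[2] == lab
        }, logical(1))]
        as.matrix(sub[, cols, drop = FALSE])
      }
      marks[[m]] <- list(ip = get_mat("IP"), input = get_mat("input"))
    }
    out[[chr]] <- structure(list(chrom = chr,
                                 positions = as.integer(sub$position),
                                 marks = marks),
                            class = "chip_experiment")
  }
  out
}

#' Read a genes x tissues expression matrix from TSV
#' @param path TSV path; first column must be `gene_id`.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "gene_id") {
    tm_stop("expression table must start with a 'gene_id' column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(m < 0)) tm_stop("expression values must be non-negative")
  m
}

#' Write an expression matrix as TSV
#' @param expression Matrix genes x tissues with gene-id row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
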