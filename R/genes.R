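#' Read gene annotations from BED or GFF3
#'
#' Produces a unified gene table in 0-based half-open coordinates.  BED
#' input (BED4+) is taken as-is; GFF3 input keeps `gene` features only and
#' converts its 1-based closed coordinates (`start - 1`, `end`).  Records
#' whose interval is inverted or empty after conversion are rejected with a
#' warning, as are duplicated records.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A data.frame of class `gene_set` with columns `contig`, `start`,
#'   `end`, `strand`, `gene`.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("gene annotation not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "bed") {
    bad <- vapply(fields, length, integer(1)) < 3L
    if (any(bad)) warning(sprintf("%d malformed BED line(s) skipped", sum(bad)))
    fields <- fields[!bad]
    g <- data.frame(
      contig = vapply(fields, `[`, character(1), 1L),
      start = as.integer(vapply(fields, `[`, character(1), 2L)),
      end = as.integer(vapply(fields, `[`, character(1), 3L)),
      strand = vapply(fields, function(x)
        if (length(x) >= 6L && x[6L] %in% c("+", "-")) x[6L] else "*",
        character(1)),
      gene = vapply(fields, function(x)
        if (length(x) >= 4L) x[4L] else NA_character_, character(1)),
      stringsAsFactors = FALSE)
  } else {
    n_col <- vapply(fields, length, integer(1))
    fields <- fields[n_col >= 9L]
    type <- vapply(fields, `[`, character(1), 3L)
    fields <- fields[type == "gene"]
    attr_name <- function(x) {
      a <- paste0(";", x[9L])
      for (key in c(";Name=", ";gene_name=", ";ID=")) {
        m <- regexpr(paste0(key, "[^;]*"), a)
        if (m > 0L) return(substring(regmatches(a, m), nchar(key) + 1L))
      }
      NA_character_
    }
    g <- data.frame(
      contig = vapply(fields, `[`, character(1), 1L),
      start = as.integer(vapply(fields, `[`, character(1), 4L)) - 1L,
      end = as.integer(vapply(fields, `[`, character(1), 5L)),
      strand = vapply(fields, `[`, character(1), 7L),
      gene = vapply(fields, attr_name, character(1)),
      stringsAsFactors = FALSE)
  }
  g$gene[is.na(g$gene)] <- sprintf("gene_%d", which(is.na(g$gene)))
  bad <- g$start >= g$end
  if (any(bad)) {
    warning(sprintf("%d record(s) with start >= end rejected", sum(bad)))
    g <- g[!bad, , drop = FALSE]
  }
  dup <- duplicated(g[, c("contig", "start", "end", "gene")])
  if (any(dup)) {
    warning(sprintf("%d duplicated gene record(s) removed", sum(dup)))
    g <- g[!dup, , drop = FALSE]
  }
  rownames(g) <- NULL
  class(g) <- c("gene_set", "data.frame")
  g
}

#' Build a gene set from vectors
#'
#' @param contig,start,end,strand,gene per-gene fields; coordinates 0-based
#'   half-open.
#' @return A `gene_set` data.frame.
#' @export
gene_set <- function(contig, start, end, gene,
                     strand = rep("*", length(contig))) {
  if (any(start >= end)) stop_input("gene intervals must satisfy start < end")
  g <- data.frame(contig = contig, start = as.integer(start),
                  end = as.integer(end), strand = strand, gene = gene,
                  stringsAsFactors = FALSE)
  class(g) <- c("gene_set", "data.frame")
  g
}

# genes whose interval comes within flank_bp of [start1, end1] (1-based
# closed query interval on `contig`); gene coordinates are 0-based half-open
genes_near <- function(genes, contig, start1, end1, flank_bp) {
  if (is.null(genes) || nrow(genes) == 0L) return(character(0))
  q_start0 <- start1 - 1L - flank_bp
  q_end0 <- end1 + flank_bp
  hit <- genes$contig == contig & genes$start < q_end0 & genes$end > q_start0
  unique(genes$gene[hit])
}
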