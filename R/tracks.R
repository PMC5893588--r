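# Deterministic TSV writers.  Every file starts with a "##sweepscan" header
# recording the package version, the seed and the stage parameters (the
# reproducibility contract), then a "#"-prefixed column header.  Floats are
# written at 6 significant digits; no timestamps, so identical runs produce
# byte-identical files.

format_meta <- function(params) {
  if (length(params) == 0L) return("")
  flat <- unlist(params)
  paste(sprintf("%s=%s", names(flat),
                vapply(flat, function(v)
                  if (is.numeric(v)) sprintf("%.6g", v) else as.character(v),
                  character(1))),
        collapse = " ")
}

#' Write a per-site score track as TSV
#'
#' @param x a data.frame whose first two columns are `contig` and `pos`.
#' @param path output path.
#' @param params named list of parameters recorded in the `##` header
#'   (include the seed here).
#' @return Invisibly, `path`.
#' @export
write_track <- function(x, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##sweepscan %s %s",
                     as.character(packageVersion("sweepscan")),
                     format_meta(params)), con)
  writeLines(paste0("#", paste(colnames(x), collapse = "\t")), con)
  if (nrow(x) > 0L) {
    cols <- lapply(x, function(col) {
      if (is.double(col)) sprintf("%.6g", col)
      else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a track written by [write_track()]
#' @param path file path.
#' @return A data.frame (header comments skipped, column names restored).
#' @export
read_track <- function(path) {
  lines <- readLines(path, n = 5L)
  hdr <- grep("^#[^#]", lines, value = TRUE)[1L]
  cn <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1L]]
  out <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  colnames(out) <- cn
  out
}

#' Write an f3 result as a plain-text report plus a JSON twin
#' @param x an `f3_result` from [f3()].
#' @param path output path for the text report; the JSON twin gets
#'   extension `.json`.
#' @param params named list recorded in the header.
#' @return Invisibly, the two paths.
#' @export
write_f3_report <- function(x, path, params = list()) {
  con <- file(path, "w")
  writeLines(c(
    sprintf("##sweepscan %s %s",
            as.character(packageVersion("sweepscan")), format_meta(params)),
    sprintf("f3(%s; %s, %s)", x$pops["C"], x$pops["A"], x$pops["B"]),
    sprintf("f3\t%.6g", x$f3),
    sprintf("se\t%.6g", x$se),
    sprintf("z\t%.6g", x$z),
    sprintf("n_blocks\t%d", x$n_blocks),
    sprintf("n_snps\t%d", x$n_snps)), con)
  close(con)
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(pops = as.list(x$pops), f3 = x$f3, se = x$se, z = x$z,
         n_blocks = x$n_blocks, n_snps = x$n_snps),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, json_path))
}
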