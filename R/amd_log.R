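#' Per-frame boost record series
#'
#' One record per trajectory snapshot: the unboosted total potential `V_P`
#' and dihedral energy `V_D`, and the boost energies `dV_P` (added to the
#' whole potential) and `dV_D` (added to the torsional term), all in
#' kcal/mol. The total applied boost per frame is `dV_P + dV_D`; depending
#' on the iamd mode either term may be identically zero.
#'
#' @param step Integer step indices, strictly increasing.
#' @param V_P,V_D Unboosted energies (kcal/mol).
#' @param dV_P,dV_D Boost energies (kcal/mol, >= 0).
#' @param mode iamd mode tag (1, 2 or 3); if `NA`, inferred from which
#'   boost columns are non-zero.
#' @return Object of class `boost_series`: a data.frame with columns
#'   `step`, `V_P`, `V_D`, `dV_P`, `dV_D` and attribute `mode`.
#' @export
boost_series <- function(step = integer(), V_P = numeric(),
                         V_D = numeric(), dV_P = numeric(),
                         dV_D = numeric(), mode = NA_integer_) {
  n <- length(step)
  stopifnot(length(V_P) == n, length(V_D) == n,
            length(dV_P) == n, length(dV_D) == n)
  if (n > 1 && any(diff(step) <= 0))
    stop("step indices must be strictly increasing")
  if (any(dV_P < 0) || any(dV_D < 0))
    stop("boost energies must be >= 0")
  if (is.na(mode) && n > 0) {
    mode <- if (all(dV_D == 0) && any(dV_P > 0)) 1L
            else if (all(dV_P == 0) && any(dV_D > 0)) 2L
            else 3L
  }
  structure(data.frame(step = as.integer(step), V_P = V_P, V_D = V_D,
                       dV_P = dV_P, dV_D = dV_D),
            mode = as.integer(mode),
            class = c("boost_series", "data.frame"))
}

#' Total applied boost per frame
#'
#' @param series A `boost_series`.
#' @param which `"total"` (default): `dV_P + dV_D`, the full boost applied
#'   to each snapshot; `"dihedral"`: `dV_D` only.
#' @return Numeric vector of boost energies (kcal/mol).
#' @export
applied_boost <- function(series, which = c("total", "dihedral")) {
  stopifnot(inherits(series, "boost_series"))
  which <- match.arg(which)
  if (which == "total") series$dV_P + series$dV_D else series$dV_D
}

#' Parse an amd.log boost file
#'
#' Native dialect: lines beginning with `#` are comments (a
#' `# iamd=<mode>` comment sets the mode tag); data lines hold the
#' whitespace-separated columns `step V_P V_D dV_P dV_D` in kcal/mol.
#' Amber-style logs with a different column layout can be ingested by
#' passing `columns`, a named integer vector giving 1-based column numbers
#' for at least `step`, `dV_P` and `dV_D` (and optionally `V_P`, `V_D`,
#' which default to 0 when unmapped).
#'
#' @param path Input file.
#' @param columns Optional named column mapping (see above).
#' @return A [boost_series()].
#' @export
parse_amd_log <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  mode <- NA_integer_
  m <- regmatches(lines, regexpr("iamd\\s*=\\s*[123]", lines))
  if (length(m)) mode <- as.integer(sub(".*=\\s*", "", m[1]))
  data_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(data_idx) == 0L) return(boost_series(mode = mode))
  if (is.null(columns))
    columns <- c(step = 1L, V_P = 2L, V_D = 3L, dV_P = 4L, dV_D = 5L)
  need <- c("step", "dV_P", "dV_D")
  if (!all(need %in% names(columns)))
    stop("column mapping must name at least: ", paste(need, collapse = ", "))
  rows <- vector("list", length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (max(columns) > length(f))
      stop(sprintf("line %d: expected >= %d fields, found %d",
                   i, max(columns), length(f)))
    v <- suppressWarnings(as.numeric(f[columns]))
    if (any(is.na(v)))
      stop(sprintf("line %d: non-numeric field", i))
    names(v) <- names(columns)
    rows[[k]] <- v
  }
  tab <- do.call(rbind, rows)
  get <- function(nm) if (nm %in% colnames(tab)) tab[, nm] else rep(0, nrow(tab))
  step <- tab[, "step"]
  if (nrow(tab) > 1 && any(diff(step) <= 0))
    stop("step indices must be strictly increasing")
  boost_series(step = step, V_P = get("V_P"), V_D = get("V_D"),
               dV_P = tab[, "dV_P"], dV_D = tab[, "dV_D"], mode = mode)
}

#' Write a boost series in the amd.log dialect
#'
#' Full-precision output so that `parse_amd_log(write_amd_log(x))`
#' reproduces every numeric field exactly.
#'
#' @param series A `boost_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_amd_log <- function(series, path) {
  stopifnot(inherits(series, "boost_series"))
  if (any(series$dV_P < 0) || any(series$dV_D < 0))
    stop("refusing to write negative boost energies")
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  mode <- attr(series, "mode")
  hdr <- c("# amdmem boost log",
           "# step V_P V_D dV_P dV_D (kcal/mol)")
  if (!is.na(mode)) hdr <- c(hdr, sprintf("# iamd=%d", mode))
  body <- if (nrow(series) > 0)
    paste(series$step, fmt(series$V_P), fmt(series$V_D),
          fmt(series$dV_P), fmt(series$dV_D)) else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a results table as TSV with a '#' header line
#'
#' @param df A data.frame.
#' @param path Output file.
#' @param comment Header text naming columns and units (written after `# `).
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path,
                             comment = paste(names(df), collapse = "\t")) {
  con <- file(path, open = "wt"); on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
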