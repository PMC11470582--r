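#' Diffusion-weighting scheme: b-values and excitation counts
#'
#' A `b_scheme` pairs an ordered vector of b-values (s/mm^2) with the number
#' of excitations (NEX) averaged at each b. The NEX schedule matters twice:
#' it sets the per-b noise level of simulated magnitude data (averaging `n`
#' excitations scales the noise SD by `1/sqrt(n)`), and it optionally
#' supplies weights for the least-squares fit.
#'
#' @param b Numeric vector of b-values in s/mm^2; strictly increasing,
#'   starting at 0.
#' @param nex Positive integer vector of excitation counts, one per b.
#'   Defaults to 1 for every b.
#' @return An object of class `b_scheme`: a list with elements `b` and `nex`.
#' @examples
#' sch <- b_scheme(c(0, 400, 800))
#' default_scheme()
#' @export
b_scheme <- function(b, nex = rep(1L, length(b))) {
  b <- as.numeric(b)
  nex <- as.integer(nex)
  if (length(b) == 0L) stop("scheme must contain at least one b-value")
  if (length(b) != length(nex)) {
    stop(sprintf("lengths differ: %d b-values vs %d NEX entries",
                 length(b), length(nex)))
  }
  if (b[1] != 0) stop("first b-value must be 0 (the S(0) reference)")
  if (any(diff(b) <= 0)) stop("b-values must be strictly increasing")
  if (any(is.na(nex)) || any(nex < 1L)) stop("NEX entries must be positive integers")
  structure(list(b = b, nex = nex), class = "b_scheme")
}

#' Default 16-point breast DWI protocol
#'
#' The packaged acquisition scheme: 16 b-values from 0 to 3000 s/mm^2 with
#' the clinical NEX schedule that spends more averages at high b, where the
#' magnitude signal is weakest.
#'
#' @return A [b_scheme] with 16 entries, maximum b = 3000 s/mm^2.
#' @export
default_scheme <- function() {
  b_scheme(
    b   = c(0, 10, 20, 30, 50, 70, 100, 150, 200, 400,
            800, 1200, 1500, 2000, 2500, 3000),
    nex = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 3, 6, 7, 7)
  )
}

#' @export
print.b_scheme <- function(x, ...) {
  cat(sprintf("DWI scheme: %d b-values, 0-%g s/mm^2\n", length(x$b), max(x$b)))
  print(data.frame(b = x$b, nex = x$nex), row.names = FALSE)
  invisible(x)
}

#' @export
length.b_scheme <- function(x) length(x$b)

#' Read a scheme from FSL-style sidecar files
#'
#' `.bval` holds whitespace-separated b-values; a parallel `.nex` file (same
#' layout) holds the excitation counts. If `nex_path` is missing or `NULL`,
#' NEX defaults to 1 everywhere.
#'
#' @param bval_path Path to the `.bval` file.
#' @param nex_path Optional path to the `.nex` file.
#' @return A [b_scheme]. Unsorted b-values are reordered with a warning.
#' @export
read_scheme <- function(bval_path, nex_path = NULL) {
  b <- scan(bval_path, what = numeric(), quiet = TRUE)
  nex <- if (!is.null(nex_path) && file.exists(nex_path)) {
    scan(nex_path, what = numeric(), quiet = TRUE)
  } else {
    rep(1, length(b))
  }
  if (length(b) != length(nex)) {
    stop(sprintf("sidecar mismatch: %d b-values but %d NEX entries",
                 length(b), length(nex)))
  }
  if (is.unsorted(b, strictly = TRUE)) {
    warning("b-values not strictly increasing; reordering")
    o <- order(b)
    b <- b[o]; nex <- nex[o]
  }
  b_scheme(b, nex)
}

#' Write a scheme as `.bval`/`.nex` sidecars
#'
#' @param scheme A [b_scheme].
#' @param bval_path,nex_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_scheme <- function(scheme, bval_path, nex_path) {
  writeLines(paste(format(scheme$b, trim = TRUE), collapse = " "), bval_path)
  writeLines(paste(scheme$nex, collapse = " "), nex_path)
  invisible(c(bval_path, nex_path))
}

#' Read a protocol configuration (YAML or JSON)
#'
#' The file carries `b` and `nex` lists plus optional model options; the
#' packaged default (`system.file("extdata", "default_protocol.yaml",
#' package = "maddwi")`) replicates the 16-point clinical scheme.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` protocol file.
#' @return A [b_scheme].
#' @export
read_protocol <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$b)) stop("protocol file lacks a 'b' entry")
  nex <- if (is.null(cfg$nex)) rep(1L, length(cfg$b)) else cfg$nex
  b_scheme(unlist(cfg$b), unlist(nex))
}
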