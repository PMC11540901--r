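# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generation never perturbs the session stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_input <- function(...) stop(..., call. = FALSE)

is_scalar_int <- function(x) {
  length(x) == 1L && !is.na(x) && is.numeric(x) && x == as.integer(x)
}

# strict logical coercion from CSV cells: "", NA -> NA; 0/1/TRUE/FALSE otherwise
parse_flag <- function(x, column) {
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  x_low <- tolower(x)
  out[x_low %in% c("1", "true", "t")] <- TRUE
  out[x_low %in% c("0", "false", "f")] <- FALSE
  bad <- !(x_low %in% c("1", "true", "t", "0", "false", "f", "", "na"))
  if (any(bad)) {
    stop_input(sprintf("column '%s': non-boolean value '%s' (row %d)",
                       column, x[which(bad)[1]], which(bad)[1]))
  }
  as.logical(out)
}

parse_int <- function(x, column) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & x != "" & tolower(x) != "na" &
    (is.na(out) | out != floor(out))
  if (any(bad)) {
    stop_input(sprintf("column '%s': non-integer value '%s' (row %d)",
                       column, x[which(bad)[1]], which(bad)[1]))
  }
  out[x == "" | tolower(x) == "na"] <- NA
  as.integer(out)
}

parse_num <- function(x, column) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & x != "" & tolower(x) != "na" & is.na(out)
  if (any(bad)) {
    stop_input(sprintf("column '%s': non-numeric value '%s' (row %d)",
                       column, x[which(bad)[1]], which(bad)[1]))
  }
  out[x == "" | tolower(x) == "na"] <- NA
  out
}

fmt_flag <- function(x) ifelse(is.na(x), "", ifelse(x, "1", "0"))

fmt_val <- function(x) ifelse(is.na(x), "", as.character(x))

extdata <- function(file) {
  path <- system.file("extdata", file, package = "respstrat")
  if (!nzchar(path)) stop_input(sprintf("shipped config '%s' not found", file))
  path
}
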