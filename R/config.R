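# Minimal reader for the flat [section] / key = value configuration
# dialect used by the command-line tools. Supports numbers, booleans,
# quoted strings and flat arrays; nothing pre-installed parses this
# format, and the subset is deliberately small.

#' Read a key-value configuration file
#'
#' Parses a flat TOML-dialect file: `[section]` headers, `key = value`
#' pairs, `#` comments. Values may be numbers, `true`/`false`, quoted
#' strings, or flat arrays `[1, 2, 3]`. Recognized sections for batch
#' configuration are `[constants]`, `[grid]`, `[solver]` and `[batch]`.
#'
#' @param path file path.
#' @return A named list of sections, each a named list of values; keys
#'   before any section header live at the top level.
#' @export
readConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  parseValue <- function(s, ln) {
    s <- trimws(s)
    if (s %in% c("true", "false")) return(s == "true")
    if (grepl('^".*"$', s) || grepl("^'.*'$", s)) {
      return(substr(s, 2, nchar(s) - 1))
    }
    if (grepl("^\\[.*\\]$", s)) {
      inner <- trimws(substr(s, 2, nchar(s) - 1))
      if (inner == "") return(numeric(0))
      parts <- strsplit(inner, ",")[[1]]
      return(unlist(lapply(parts, parseValue, ln = ln)))
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("config line ", ln, ": cannot parse value '", s, "'")
    v
  }
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    s <- trimws(raw)
    if (s == "") next
    if (grepl("^\\[.*\\]$", s)) {
      section <- trimws(substr(s, 2, nchar(s) - 1))
      if (section == "") stop("config line ", ln, ": empty section name")
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    eq <- regexpr("=", s, fixed = TRUE)
    if (eq < 0) stop("config line ", ln, ": expected 'key = value'")
    key <- trimws(substr(s, 1, eq - 1))
    if (key == "") stop("config line ", ln, ": empty key")
    val <- parseValue(substr(s, eq + 1, nchar(s)), ln)
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

#' Build simulation objects from a configuration list
#'
#' Maps the `[constants]`, `[grid]`, `[solver]` and `[batch]` sections of
#' a parsed configuration onto [physicalConstants()], [sizeGrid()],
#' solver options and [batchConditions()]. Any omitted key takes the
#' package default; `constants.csat` is required.
#'
#' @param cfg a list from [readConfig()].
#' @return A list with `constants`, `grid`, `solverOpts` and (when a
#'   `[batch]` section is present) `conditions`.
#' @export
configToObjects <- function(cfg) {
  cc <- cfg$constants
  if (is.null(cc$csat)) {
    stop("configuration error: [constants] must provide csat")
  }
  constants <- do.call(physicalConstants, cc)
  gg <- cfg$grid
  grid <- sizeGrid(nBins = gg$nBins %||% 300,
                   Lmin = gg$Lmin %||% 1e-9,
                   Lmax = gg$Lmax %||% 50e-6,
                   spacing = gg$spacing %||% "geometric")
  solverOpts <- cfg$solver %||% list()
  conditions <- NULL
  if (!is.null(cfg$batch)) {
    conditions <- batchConditions(cfg$batch$c0,
                                  cfg$batch$duration_min * 60, constants)
  }
  list(constants = constants, grid = grid, solverOpts = solverOpts,
       conditions = conditions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
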