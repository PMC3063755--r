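#' Parse a physical quantity with an SI unit suffix
#'
#' Converts strings such as `"2cm"`, `"13uH"`, `"200uF"`, `"0.09ohm"` or
#' `"36V"` to a numeric value in base SI units (m, H, F, Ohm, V, A, s).
#' Plain numerics pass through unchanged, so config files may use either
#' style. Recognised prefixes: `G M k c m u n p` (and `µ` as alias of `u`).
#'
#' @param x character or numeric scalar/vector.
#' @return numeric vector in base SI units.
#' @examples
#' parse_quantity("2cm")    # 0.02
#' parse_quantity("13uH")   # 1.3e-05
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  stopifnot(is.character(x))
  vapply(x, parse_quantity1, numeric(1), USE.NAMES = FALSE)
}

parse_quantity1 <- function(s) {
  s <- trimws(s)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*([A-Za-zµ]*)$", s))[[1]]
  if (length(m) == 0 || m[2] == "")
    stop("cannot parse quantity: '", s, "'", call. = FALSE)
  val <- as.numeric(m[2])
  if (is.na(val)) stop("cannot parse quantity: '", s, "'", call. = FALSE)
  unit <- m[3]
  if (unit == "") return(val)
  # strip the base unit from the end, what remains is the prefix
  bases <- c("Ohm", "ohm", "H", "F", "V", "A", "s", "m", "J")
  base <- NULL
  for (b in bases) {
    if (endsWith(unit, b)) { base <- b; break }
  }
  if (is.null(base)) stop("unknown unit in '", s, "'", call. = FALSE)
  pre <- substr(unit, 1L, nchar(unit) - nchar(base))
  scale <- if (pre == "") 1 else switch(pre,
    "G" = 1e9, "M" = 1e6, "k" = 1e3, "c" = 1e-2,
    "m" = 1e-3, "u" = 1e-6, "µ" = 1e-6, "n" = 1e-9, "p" = 1e-12,
    stop("unknown prefix '", pre, "' in '", s, "'", call. = FALSE))
  val * scale
}
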