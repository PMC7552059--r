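#' Elemental monoisotopic masses (Da)
#'
#' Monoisotopic masses of the six elements handled by the pipeline,
#' fixed in code so mass arithmetic is reproducible to the last digit.
#' Carbon is exactly 12 by definition of the unified atomic mass scale.
#'
#' @format Named numeric vector with elements `c`, `h`, `n`, `o`, `s`, `p`.
#' @export
ELEMENT_MASSES <- c(
  c = 12.0,
  h = 1.007825032,
  n = 14.003074005,
  o = 15.994914620,
  s = 31.972071174,
  p = 30.973761998
)

#' Proton mass (Da)
#'
#' Mass added to an \[M-H\]- ion m/z to recover the neutral monoisotopic
#' mass (equivalently the hydrogen atom mass minus the electron mass).
#'
#' @export
PROTON_MASS <- 1.00727646688

.ELEMENTS <- c("c", "h", "n", "o", "s", "p")

# Hill order: C, H, then remaining element symbols alphabetically.
.HILL_ORDER <- c("c", "h", "n", "o", "p", "s")
.HILL_SYMBOL <- c(c = "C", h = "H", n = "N", o = "O", p = "P", s = "S")

.empty_formula_df <- function(n = 0L) {
  out <- data.frame(
    c = integer(n), h = integer(n), n = integer(n),
    o = integer(n), s = integer(n), p = integer(n)
  )
  out
}

#' Coerce input to a formula count table
#'
#' Accepts either a data frame with integer columns `c,h,n,o,s,p` or a
#' character vector of Hill-notation formula strings.
#'
#' @param x formulas as data frame or character vector.
#' @return data frame with columns `c,h,n,o,s,p`.
#' @export
as_formula_df <- function(x) {
  if (is.character(x)) {
    return(parse_formula(x))
  }
  if (is.data.frame(x)) {
    missing <- setdiff(.ELEMENTS, names(x))
    if (length(missing) > 0) {
      stop("formula table lacks element column(s): ",
           paste(missing, collapse = ", "))
    }
    out <- x[.ELEMENTS]
    for (el in .ELEMENTS) out[[el]] <- as.integer(out[[el]])
    return(out)
  }
  stop("cannot interpret object of class '", class(x)[1], "' as formulas")
}

#' Parse molecular formula strings
#'
#' Parses Hill-notation CHNOSP formula strings (e.g. `"C6H12O6"`,
#' `"C3H7NO2"`) into element counts. Only the elements C, H, N, O, S and P
#' are allowed; an implicit count of 1 is understood for a symbol without a
#' subscript.
#'
#' @param text character vector of formula strings.
#' @return data frame with one row per input and integer columns
#'   `c,h,n,o,s,p`.
#' @examples
#' parse_formula(c("C6H12O6", "C3H7NO2"))
#' @export
parse_formula <- function(text) {
  if (length(text) == 0) return(.empty_formula_df(0L))
  if (!is.character(text)) stop("'text' must be a character vector")
  if (anyNA(text) || any(!nzchar(text))) {
    stop("formula strings must be non-empty and non-missing")
  }
  mat <- matrix(0L, nrow = length(text), ncol = 6,
                dimnames = list(NULL, .ELEMENTS))
  for (i in seq_along(text)) {
    s <- text[i]
    tokens <- regmatches(s, gregexpr("[A-Z][a-z]*[0-9]*", s))[[1]]
    if (sum(nchar(tokens)) != nchar(s)) {
      stop("malformed formula string: '", s, "'")
    }
    for (tok in tokens) {
      sym <- sub("[0-9]*$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      el <- tolower(sym)
      if (!(el %in% .ELEMENTS) || nchar(sym) != 1) {
        stop("unknown element symbol '", sym, "' in formula '", s, "'")
      }
      if (mat[i, el] != 0L) {
        stop("element '", sym, "' repeated in formula '", s, "'")
      }
      count <- if (nzchar(cnt)) suppressWarnings(as.integer(cnt)) else 1L
      if (is.na(count) || count < 1L) {
        stop("malformed count '", cnt, "' for element '", sym,
             "' in formula '", s, "'")
      }
      mat[i, el] <- count
    }
    if (mat[i, "c"] < 1L) stop("formula '", s, "' contains no carbon")
    if (mat[i, "h"] < 1L) stop("formula '", s, "' contains no hydrogen")
  }
  as.data.frame(mat)
}

#' Format formulas as Hill-notation strings
#'
#' Canonical text form: C first, H second, then N, O, P, S alphabetically;
#' zero counts omitted, count 1 written without a subscript. Inverse of
#' [parse_formula()].
#'
#' @param f formulas (data frame of counts or character vector).
#' @return character vector of Hill strings.
#' @export
format_formula <- function(f) {
  f <- as_formula_df(f)
  if (nrow(f) == 0) return(character(0))
  out <- character(nrow(f))
  for (el in .HILL_ORDER) {
    cnt <- f[[el]]
    piece <- ifelse(cnt == 0L, "",
                    ifelse(cnt == 1L, .HILL_SYMBOL[[el]],
                           paste0(.HILL_SYMBOL[[el]], cnt)))
    out <- paste0(out, piece)
  }
  out
}

#' Neutral monoisotopic mass of a formula
#'
#' @param f formulas (data frame of counts or character vector).
#' @return numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("C6H12O6") # 180.0633881
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula_df(f)
  as.numeric(as.matrix(f[.ELEMENTS]) %*% ELEMENT_MASSES[.ELEMENTS])
}

#' Convert measured m/z of an \[M-H\]- ion to neutral mass
#'
#' Singly deprotonated ions are assumed throughout (negative-mode
#' electrospray): M = m/z + proton mass.
#'
#' @param mz numeric vector of m/z values (Da), all > 0.
#' @return neutral monoisotopic masses (Da).
#' @export
mz_to_neutral_mass <- function(mz) {
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("m/z values must be positive")
  mz + PROTON_MASS
}

#' Theoretical \[M-H\]- m/z of a neutral formula
#'
#' @param f formulas (data frame of counts or character vector).
#' @return numeric vector of ion m/z values (Da).
#' @export
formula_to_mz <- function(f) {
  monoisotopic_mass(f) - PROTON_MASS
}
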