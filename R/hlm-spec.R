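# Model-term mini-language for two-level gradient models.
#
# Fixed terms come from {1, d, d2, u, d:u, d2:u}; random terms from
# {1, d, d2}. "d^2", "I(d^2)" and "u:d" style aliases are accepted and
# canonicalized. Columns are always assembled in the canonical order above,
# independent of the order the user wrote.

FIXED_TERMS  <- c("1", "d", "d2", "u", "d:u", "d2:u")
RANDOM_TERMS <- c("1", "d", "d2")

parse_terms <- function(spec, allowed, what) {
  if (is.null(spec) || identical(spec, "") || identical(spec, "0"))
    return(character(0))
  raw <- strsplit(spec, "+", fixed = TRUE)[[1L]]
  out <- character(0)
  for (t in raw) {
    t <- gsub("[[:space:]]", "", t)
    if (t == "") next
    t <- gsub("I\\((.*)\\)", "\\1", t)
    t <- gsub("\\^2", "2", t)
    parts <- strsplit(t, ":", fixed = TRUE)[[1L]]
    if (length(parts) == 2L && parts[1L] == "u") parts <- rev(parts)
    t <- paste(parts, collapse = ":")
    if (!t %in% allowed)
      stop("unknown ", what, " term `", t, "`; allowed: ",
           paste(allowed, collapse = ", "))
    out <- c(out, t)
  }
  unique(out)
}

#' Specify a two-level linear mixed model for gradient data
#'
#' @param fixed fixed-effect terms as a `+`-separated string over
#'   `1, d, d2 (= d squared), u, d:u, d2:u`, e.g. `"1 + d + u + d:u"`.
#' @param random random-effect terms over `1, d, d2`, e.g. `"1 + d"`;
#'   `NULL` or `""` for no random part (ordinary least squares).
#' @param method `"ML"` or `"REML"`.
#' @details The intercept is mandatory in the fixed part and in any
#'   non-empty random part, and every term requires its lower-order
#'   marginals: `d2` needs `d`, `d:u` needs both `d` and `u`, and `d2:u`
#'   needs `d2` and `d:u`.
#' @return An object of class `"lmm_spec"`.
#' @export
lmm_spec <- function(fixed, random = "1", method = c("ML", "REML")) {
  method <- match.arg(method)
  f <- parse_terms(fixed, FIXED_TERMS, "fixed")
  r <- parse_terms(random, RANDOM_TERMS, "random")
  if (!"1" %in% f) stop("the fixed part must include the intercept `1`")
  if (length(r) && !"1" %in% r) stop("a non-empty random part must include the intercept `1`")
  need <- list(d2 = "d", "d:u" = c("d", "u"), "d2:u" = c("d2", "d:u"))
  for (t in names(need))
    if (t %in% f && !all(need[[t]] %in% f))
      stop("fixed term `", t, "` requires its lower-order term(s): ",
           paste(setdiff(need[[t]], f), collapse = ", "))
  if ("d2" %in% r && !"d" %in% r)
    stop("random term `d2` requires the random term `d`")
  f <- FIXED_TERMS[FIXED_TERMS %in% f]
  r <- RANDOM_TERMS[RANDOM_TERMS %in% r]
  structure(list(fixed = f, random = r, method = method), class = "lmm_spec")
}

#' @export
print.lmm_spec <- function(x, ...) {
  cat(sprintf("lmm spec: fixed = %s; random = %s; %s\n",
              paste(x$fixed, collapse = " + "),
              if (length(x$random)) paste(x$random, collapse = " + ") else "(none)",
              x$method))
  invisible(x)
}

# Column builders: term -> function(d, u)
term_column <- function(term, d, u) {
  switch(term,
    "1" = rep(1, length(d)),
    "d" = d,
    "d2" = d^2,
    "u" = u,
    "d:u" = d * u,
    "d2:u" = d^2 * u,
    stop("bad term ", term))
}

build_X <- function(terms, d, u) {
  if (!length(terms)) return(matrix(0, length(d), 0L))
  m <- vapply(terms, term_column, numeric(length(d)), d = d, u = u)
  if (is.null(dim(m))) m <- matrix(m, nrow = length(d), dimnames = list(NULL, terms))
  m
}
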