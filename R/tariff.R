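#' EQ-5D-3L value set (Dolan MVH-A1 UK tariff)
#'
#' The UK time-trade-off value set for the three-level EQ-5D. A health state is
#' a profile of five dimensions (mobility, self-care, usual activities,
#' pain/discomfort, anxiety/depression), each at level 1 (no problems), 2
#' (some problems) or 3 (extreme problems). Its utility is
#' \deqn{U = 1 - c\,[\text{any level} > 1] - \sum_d \delta_{d,\ell_d} -
#'   N3\,[\text{any level} = 3]}
#' with constant \eqn{c = 0.081}, dimension/level decrements
#' \eqn{\delta_{d,\ell}}, and the N3 term 0.269. Full health (1,1,1,1,1) has
#' utility 1; the worst state (3,3,3,3,3) has utility -0.594.
#'
#' @param path Path to a tariff coefficient CSV. Defaults to the MVH-A1 table
#'   bundled with the package. Alternative national tariffs with the same
#'   constant + per-dimension-decrement + N3 structure can be substituted by
#'   pointing `path` at a file with the same columns
#'   (`term`, `dimension`, `level`, `decrement`).
#' @return An object of class `eq5d_tariff`: a list with elements `constant`,
#'   `n3`, and `decrements` (a 5 x 2 matrix, rows = dimensions, columns =
#'   levels 2 and 3).
#' @export
#' @examples
#' tariff <- dolan_tariff()
#' eq5d_utility(c(1, 1, 1, 1, 1), tariff)
#' eq5d_utility(c(3, 3, 3, 3, 3), tariff)
dolan_tariff <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mvh_a1_tariff.csv", package = "netcea",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("term", "dimension", "level", "decrement")
  if (!all(need %in% names(tab))) {
    stop("tariff file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dims <- unique(tab$dimension[tab$term == "decrement"])
  if (length(dims) != 5L) {
    stop("tariff file must define decrements for exactly 5 dimensions",
         call. = FALSE)
  }
  dec <- matrix(NA_real_, nrow = 5L, ncol = 2L,
                dimnames = list(dims, c("2", "3")))
  for (i in seq_len(nrow(tab))) {
    if (tab$term[i] == "decrement") {
      dec[tab$dimension[i], as.character(tab$level[i])] <- tab$decrement[i]
    }
  }
  if (anyNA(dec)) stop("tariff file is missing decrement entries", call. = FALSE)
  out <- structure(
    list(
      constant = tab$decrement[tab$term == "constant"][1],
      n3 = tab$decrement[tab$term == "n3"][1],
      decrements = dec
    ),
    class = "eq5d_tariff"
  )
  if (any(unlist(out[c("constant", "n3")]) <= 0) || any(dec <= 0)) {
    stop("all tariff decrements must be positive", call. = FALSE)
  }
  out
}

#' @export
print.eq5d_tariff <- function(x, ...) {
  cat("<eq5d_tariff> constant", x$constant, "| N3", x$n3, "\n")
  print(x$decrements)
  invisible(x)
}

#' Utility of EQ-5D-3L health states
#'
#' Converts five-dimension, three-level health-state profiles to preference
#' based utilities under a national tariff (by default the Dolan MVH-A1 UK
#' value set).
#'
#' @param states A length-5 integer vector (one state), a 5-column matrix or a
#'   data frame of 5 level columns (one state per row). Levels must be 1, 2
#'   or 3.
#' @param tariff An [`eq5d_tariff`][dolan_tariff] object.
#' @return A numeric vector of utilities, one per state.
#' @export
#' @examples
#' eq5d_utility(c(2, 1, 1, 1, 1)) # 0.850
eq5d_utility <- function(states, tariff = dolan_tariff()) {
  stopifnot(inherits(tariff, "eq5d_tariff"))
  if (is.data.frame(states)) states <- as.matrix(states)
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  if (ncol(states) != 5L) {
    stop("an EQ-5D state has exactly 5 dimensions", call. = FALSE)
  }
  storage.mode(states) <- "integer"
  ok <- !is.na(states) & states >= 1L & states <= 3L
  if (!all(ok | is.na(states))) {
    stop("EQ-5D levels must be in {1, 2, 3}", call. = FALSE)
  }
  dec <- tariff$decrements
  u <- rep(1, nrow(states))
  any_problem <- rowSums(states > 1L) > 0L
  any_three <- rowSums(states == 3L) > 0L
  u <- u - tariff$constant * any_problem - tariff$n3 * any_three
  for (d in 1:5) {
    lev <- states[, d]
    u <- u - ifelse(lev == 2L, dec[d, "2"], ifelse(lev == 3L, dec[d, "3"], 0))
  }
  u[rowSums(is.na(states)) > 0L] <- NA_real_
  as.numeric(u)
}

# All 243 EQ-5D-3L states as a 243 x 5 matrix.
eq5d_all_states <- function() {
  as.matrix(expand.grid(mo = 1:3, sc = 1:3, ua = 1:3, pd = 1:3, ad = 1:3))
}
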