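#' The 2 x 2 x 5 factorial vignette design
#'
#' Each hypothetical scenario shown to a respondent varies three factors:
#' `trade` (0 = no economic impact of global under-vaccination, 1 = the
#' economy shrinks by about 5\%), `risk` (0 = mutation risk does not
#' increase, 1 = it increases considerably), and `deal`, a five-level
#' description of an international agreement. The deal level determines two
#' numeric scenario variables: the number of other countries contributing
#' and the total amount (billion EUR) they contribute jointly.
#'
#' @return A data frame with one row per design cell (20 rows) and columns
#'   `trade`, `risk`, `deal`, `n_countries`, `total_amount`.
#' @examples
#' vignette_grid()
#' @export
vignette_grid <- function() {
  g <- expand.grid(deal = 0:4, risk = 0:1, trade = 0:1,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("trade", "risk", "deal")]
  cond <- deal_to_conditions(g$deal)
  rownames(g) <- NULL
  cbind(g, cond)
}

# fixed deal -> (number of countries, total billion EUR) mapping
.deal_map <- matrix(
  c(0L, 0L,
    20L, 20L,
    40L, 20L,
    20L, 40L,
    40L, 40L),
  ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("n_countries", "total_amount"))
)

#' Map deal levels to scenario variables
#'
#' Deal levels 0-4 deterministically encode how many other countries take
#' part in the international agreement and how much they contribute in
#' total: 0 -> (0, 0), 1 -> (20, 20), 2 -> (40, 20), 3 -> (20, 40),
#' 4 -> (40, 40).
#'
#' @param deal Integer vector of deal levels in `{0,...,4}`.
#' @return Data frame with columns `n_countries` (count) and
#'   `total_amount` (billion EUR), one row per input level.
#' @examples
#' deal_to_conditions(c(0, 3, 4))
#' @export
deal_to_conditions <- function(deal) {
  if (length(deal) == 0L) stop("`deal` must be non-empty")
  d <- suppressWarnings(as.integer(deal))
  bad <- is.na(d) | d < 0L | d > 4L | d != deal
  if (any(bad)) {
    stop("invalid deal level(s): ", paste(unique(deal[bad]), collapse = ", "),
         " (must be integers in 0..4)")
  }
  as.data.frame(.deal_map[d + 1L, , drop = FALSE])
}

# canonical order of the four scenario variables; X1..X4 in the analysis
.main_terms <- c("amount", "n_countries", "risk", "trade")

#' Build the mean-centered factorial design matrix
#'
#' Converts vignette assignments into the regression design used for the
#' factorial analysis: four numeric condition variables -- `amount` (total
#' amount given by other countries, billion EUR), `n_countries` (number of
#' other countries giving), `risk` and `trade` (0/1 indicators) -- each
#' centered at its realized sample mean, plus all interaction products up
#' to `interaction_order`. Interaction columns are elementwise products of
#' the centered main-effect columns and are named by joining the main
#' terms with `:` (e.g. `"amount:risk"`). With `interaction_order = 3`
#' the matrix has the 14 slope columns of the full specification (4 main
#' effects, 6 two-way and 4 three-way interactions; no four-way term).
#'
#' Centering at the realized mean makes the main-effect coefficients of
#' the interacted regression readable as average effects.
#'
#' @param assignments Data frame with columns `respondent_id`,
#'   `vignette_index`, `trade`, `risk`, `deal`.
#' @param interaction_order Highest interaction order to include (1-3).
#' @return Object of class `"vs_design"`: a list with the centered model
#'   matrix `X`, `respondent_id`, `vignette_index`, the column `centers`
#'   used, `main_terms`, and `interaction_order`.
#' @examples
#' asg <- data.frame(respondent_id = rep(1:10, each = 2),
#'                   vignette_index = rep(1:2, 10),
#'                   vignette_grid()[sample.int(20, 20, TRUE), ])
#' d <- build_design_matrix(asg)
#' colnames(d$X)
#' @export
build_design_matrix <- function(assignments, interaction_order = 3) {
  req <- c("respondent_id", "vignette_index", "trade", "risk", "deal")
  miss <- setdiff(req, names(assignments))
  if (length(miss))
    stop("assignments is missing column(s): ", paste(miss, collapse = ", "))
  if (!interaction_order %in% 1:3)
    stop("`interaction_order` must be 1, 2 or 3")
  n <- nrow(assignments)
  if (n < 2L) stop("need at least 2 observations")
  stopifnot(all(assignments$trade %in% 0:1), all(assignments$risk %in% 0:1))

  cond <- deal_to_conditions(assignments$deal)
  raw <- cbind(amount      = as.numeric(cond$total_amount),
               n_countries = as.numeric(cond$n_countries),
               risk        = as.numeric(assignments$risk),
               trade       = as.numeric(assignments$trade))

  const <- apply(raw, 2L, function(x) diff(range(x)) == 0)
  if (any(const))
    stop("degenerate design: factor(s) constant in the analysis set: ",
         paste(colnames(raw)[const], collapse = ", "))

  centers <- colMeans(raw)
  Xm <- sweep(raw, 2L, centers)

  cols <- lapply(seq_len(ncol(Xm)), function(j) Xm[, j])
  names(cols) <- .main_terms
  if (interaction_order >= 2) {
    for (ord in 2:interaction_order) {
      for (idx in utils::combn(4L, ord, simplify = FALSE)) {
        nm <- paste(.main_terms[idx], collapse = ":")
        cols[[nm]] <- Reduce(`*`, lapply(idx, function(j) Xm[, j]))
      }
    }
  }
  X <- do.call(cbind, cols)

  structure(list(X = X,
                 respondent_id = assignments$respondent_id,
                 vignette_index = assignments$vignette_index,
                 centers = centers,
                 main_terms = .main_terms,
                 interaction_order = interaction_order),
            class = "vs_design")
}

#' @export
print.vs_design <- function(x, ...) {
  cat("Centered factorial design matrix:", nrow(x$X), "observations,",
      ncol(x$X), "columns (interaction order", x$interaction_order, ")\n")
  cat("Centers:", paste(sprintf("%s=%.3f", names(x$centers), x$centers),
                        collapse = ", "), "\n")
  invisible(x)
}
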