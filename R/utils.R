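# Internal helpers shared across modules.

# Deterministic child seeds: one master seed drives every stochastic stage,
# but stages must not share RNG streams (adding a species should not perturb
# the haul positions). Offsets keep seeds within 32-bit integer range.
.child_seed <- function(seed, stage) {
  offsets <- c(environment = 101L, hauls = 211L, catches = 307L,
               traits = 401L, analysis = 503L)
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% .Machine$integer.max)
}

# Nearest grid value lookup on a sorted vector of cell centers.
# Ties (point exactly midway between two centers) resolve to the
# lower-index (smaller-value) cell.
.nearest_index <- function(x, centers) {
  if (is.unsorted(centers)) stop("grid centers must be sorted")
  if (length(centers) == 1L) return(rep(1L, length(x)))
  mids <- (centers[-1] + centers[-length(centers)]) / 2
  findInterval(x, mids, left.open = TRUE) + 1L
}

# TRUE for points beyond half a cell width from the outermost centers.
.outside_grid <- function(x, centers, resolution) {
  half <- resolution / 2 + 1e-9
  x < min(centers) - half | x > max(centers) + half
}

# Fixed-precision numeric formatting for reproducible CSV output.
.signif_cols <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

.write_csv_fixed <- function(df, path, digits = 6) {
  readr::write_csv(.signif_cols(as.data.frame(df), digits), path)
  invisible(path)
}

.assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' @importFrom rlang .data
#' @importFrom stats coef cor cor.test lm median pf pnorm pt qnorm qt
#'   quantile rbinom rlnorm rnorm runif sd setNames shapiro.test t.test
#'   var weighted.mean wilcox.test as.formula predict qsignrank psignrank
#'   logLik complete.cases p.adjust df.residual resid fitted
#' @importFrom utils head tail
NULL
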