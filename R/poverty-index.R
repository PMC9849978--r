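# Composite deprivation index: z-standardised block-level indicators, sign
# aligned so larger = more deprived, combined as a weighted mean and cut into
# lower / middle / upper classes by terciles.

#' Indicator specification table
#'
#' @param name indicator (column) names.
#' @param direction `"deprivation_up"` when larger raw values mean more
#'   deprivation (unemployment, crowding), `"deprivation_down"` when larger
#'   values mean less (literacy).
#' @param weight non-negative weights (not all zero), default 1.
#' @return data frame of class `indicator_spec`.
#' @export
indicator_spec <- function(name, direction, weight = 1) {
  direction <- match.arg(direction, c("deprivation_up", "deprivation_down"),
                         several.ok = TRUE)
  if (length(direction) == 1) direction <- rep(direction, length(name))
  if (length(weight) == 1) weight <- rep(weight, length(name))
  stopifnot(length(direction) == length(name), length(weight) == length(name))
  if (length(name) < 1) stop("at least one indicator required")
  if (any(weight < 0) || sum(weight) == 0)
    stop("weights must be non-negative and not all zero")
  out <- data.frame(name = name, direction = direction, weight = weight,
                    stringsAsFactors = FALSE)
  class(out) <- c("indicator_spec", "data.frame")
  out
}

#' Default directions for the bundled synthetic indicators
#' @export
default_indicator_specs <- function() {
  indicator_spec(
    name = c("unemployment_rate", "dependency_burden", "literacy_rate",
             "household_crowding", "population_density"),
    direction = c("deprivation_up", "deprivation_up", "deprivation_down",
                  "deprivation_up", "deprivation_up"))
}

#' Composite deprivation score and three-class labels
#'
#' Each indicator is z-standardised across blocks, sign-flipped according to
#' its direction so that larger always means more deprived, and combined as a
#' weighted mean. Blocks are then classified into lower (most deprived),
#' middle and upper classes by score terciles; class sizes differ by at most
#' one, and ties are broken by `block_id` so the classification is
#' deterministic.
#'
#' @param blocks a [census_blocks] with indicators, or a data frame with
#'   `block_id` plus indicator columns.
#' @param specs an [indicator_spec]; defaults to equal-weight specs over all
#'   indicator columns treated as `deprivation_up`.
#' @return Object of class `poverty_result`: data frame `block_id`, `score`,
#'   `class` (factor lower/middle/upper); attribute `degenerate` is TRUE when
#'   all scores tie and classes are assigned purely by the tie-break.
#' @export
composite_score <- function(blocks, specs = NULL) {
  ind <- if (inherits(blocks, "census_blocks")) blocks$indicators else blocks
  if (is.null(ind)) stop("no indicators available")
  if (!"block_id" %in% names(ind)) stop("indicators need a block_id column")
  if (is.null(specs)) {
    nm <- setdiff(names(ind), "block_id")
    specs <- indicator_spec(nm, "deprivation_up")
  }
  miss <- setdiff(specs$name, names(ind))
  if (length(miss))
    stop("indicator(s) not present: ", paste(miss, collapse = ", "))
  keep <- logical(nrow(specs))
  zs <- matrix(0, nrow(ind), nrow(specs))
  for (k in seq_len(nrow(specs))) {
    v <- ind[[specs$name[k]]]
    if (!all(is.finite(v))) stop("non-finite values in ", specs$name[k])
    if (sd(v) == 0) {
      warning("indicator ", specs$name[k], " has zero variance; dropped")
      next
    }
    keep[k] <- TRUE
    z <- (v - mean(v)) / sd(v)
    if (specs$direction[k] == "deprivation_down") z <- -z
    zs[, k] <- z
  }
  if (!any(keep)) stop("all indicators have zero variance")
  wts <- specs$weight * keep
  score <- as.vector(zs %*% wts) / sum(wts)
  n <- length(score)
  degenerate <- isTRUE(all(abs(score - score[1]) < 1e-12))
  if (degenerate)
    warning("all composite scores equal; classes assigned purely by block_id tie-break")
  # rank with deterministic tie-break: higher score = more deprived = lower class
  ord <- order(-score, ind$block_id)
  sizes <- rep(n %/% 3, 3)
  extra <- n %% 3
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  cls <- rep(c("lower", "middle", "upper"), times = sizes)
  class_vec <- character(n)
  class_vec[ord] <- cls
  out <- data.frame(block_id = ind$block_id, score = score,
                    class = factor(class_vec, levels = c("lower", "middle", "upper")),
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("poverty_result", "data.frame")
  out
}

#' @export
print.poverty_result <- function(x, ...) {
  cat("Composite deprivation:", nrow(x), "blocks; class sizes",
      paste(table(x$class), collapse = "/"), "\n")
  if (isTRUE(attr(x, "degenerate")))
    cat("  (degenerate: all scores equal, tie-break classification)\n")
  invisible(x)
}

#' Numeric coding of poverty classes for autocorrelation testing
#'
#' @param result a [composite_score()] result.
#' @param coding `"ordinal"` (lower = 3, middle = 2, upper = 1, so larger =
#'   more deprived) or `"lower_binary"` (1 for the lower class, else 0).
#' @return numeric vector aligned with the result's blocks.
#' @export
class_to_value <- function(result, coding = c("ordinal", "lower_binary")) {
  coding <- match.arg(coding)
  if (coding == "ordinal")
    unname(c(lower = 3, middle = 2, upper = 1)[as.character(result$class)])
  else
    as.numeric(result$class == "lower")
}
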