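check_vitamer_table <- function(table) {
  stopifnot(all(c("condition", "genotype", "vitamer", "replicate", "value")
                %in% names(table)))
  if (any(table$value < 0)) stop("concentrations must be non-negative")
  invisible(table)
}

vitamer_cell <- function(table, genotype, condition, vitamer) {
  v <- table$value[table$genotype == genotype &
                     table$condition == condition &
                     table$vitamer == vitamer]
  if (!length(v))
    stop("no measurements for genotype=", genotype, ", condition=", condition,
         ", vitamer=", vitamer)
  v
}

#' Fold change of a vitamer between two growth conditions
#'
#' Ratio of arithmetic replicate means (numerator condition over denominator
#' condition) for one genotype and vitamer, with a delta-method standard
#' error: for independent means `mA/mB`,
#' `se^2 = varA/(nA mB^2) + mA^2 varB/(nB mB^4)`.
#'
#' @param table Vitamer data frame (`condition`, `genotype`, `vitamer`,
#'   `replicate`, `value`).
#' @param vitamer One of the measured vitamers (e.g. `"ThDP"`).
#' @param genotype Genotype label.
#' @param condition_num,condition_den Numerator and denominator conditions.
#' @return List with `estimate`, `se`, `n_num`, `n_den`.
#' @export
fold_change <- function(table, vitamer, genotype, condition_num,
                        condition_den) {
  check_vitamer_table(table)
  a <- vitamer_cell(table, genotype, condition_num, vitamer)
  b <- vitamer_cell(table, genotype, condition_den, vitamer)
  mb <- mean(b)
  if (mb <= 0) stop("denominator mean is not positive")
  ma <- mean(a)
  va <- if (length(a) > 1) var(a) else 0
  vb <- if (length(b) > 1) var(b) else 0
  se <- sqrt(va / (length(a) * mb^2) + ma^2 * vb / (length(b) * mb^4))
  list(estimate = ma / mb, se = se, n_num = length(a), n_den = length(b))
}

#' Share of the total vitamer pool held by one vitamer
#'
#' Mean concentration of `vitamer` divided by the summed mean concentrations
#' of all three vitamers (thiamin + ThMP + ThDP) for one genotype and
#' condition, reported as a percentage. The three per-vitamer shares of a
#' cell sum to 100.
#'
#' @inheritParams fold_change
#' @param vitamer Numerator vitamer (default `"thiamin"`, i.e. the free,
#'   unphosphorylated form).
#' @param vitamers The pool components (all must be present).
#' @return Percentage (0-100).
#' @export
free_fraction <- function(table, genotype, condition, vitamer = "thiamin",
                          vitamers = c("thiamin", "ThMP", "ThDP")) {
  check_vitamer_table(table)
  if (!vitamer %in% vitamers) stop("vitamer must be one of the pool components")
  means <- vapply(vitamers, function(v)
    mean(vitamer_cell(table, genotype, condition, v)), numeric(1))
  100 * means[[vitamer]] / sum(means)
}

p_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Welch t-test between two vitamer measurement groups
#'
#' Two-sided Welch (unequal-variance) two-sample t-test between two cells of
#' the table, with a significance star label (* p<0.05, ** p<0.01,
#' *** p<0.001, ns otherwise).
#'
#' @param table Vitamer data frame.
#' @param group_a,group_b Named lists selecting each group, with elements
#'   `genotype`, `condition`, `vitamer`.
#' @return List with `t`, `df`, `p`, `stars`.
#' @export
pairwise_ttest <- function(table, group_a, group_b) {
  check_vitamer_table(table)
  pick <- function(g) vitamer_cell(table, g$genotype, g$condition, g$vitamer)
  a <- pick(group_a)
  b <- pick(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 replicates")
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, stars = p_stars(tt$p.value))
}

#' Amplification of the free cofactor pool under a bound-pool model
#'
#' If a fraction `b` of the control cofactor pool is bound to enzymes and the
#' bound amount stays constant while the total pool changes `F`-fold, the
#' free pool changes by `(F - b) / (1 - b)`. Derivation with the control
#' total normalized to 1: free' = total' - bound = F - b, free = 1 - b, so
#' free'/free = (F - b)/(1 - b). With F = 2.5 and b = 0.9 the free pool rises
#' 16-fold — a modest total-pool increase conceals an order-of-magnitude
#' change in the free concentration.
#'
#' @param F Total-pool fold change (> 0).
#' @param b Bound fraction of the control pool, in `[0, 1)`.
#' @return Fold change of the free pool.
#' @export
free_thdp_amplification <- function(F, b) {
  if (F <= 0) stop("F must be positive")
  if (b < 0 || b >= 1) stop("b must be in [0, 1)")
  if (F < b)
    stop("F (", F, ") < b (", b, "): the fixed bound pool would exceed the ",
         "new total, leaving a negative free pool")
  (F - b) / (1 - b)
}
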