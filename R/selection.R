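# Mutation-versus-selection diagnostics: the ENc-GC3s plot with Wright's
# expected curve, PR2 bias coordinates, the neutrality regression, index
# correlations, and the ENc-expression relationship.

#' Expected ENc under mutation pressure alone
#'
#' Wright's null curve relating ENc to silent-site GC content:
#' \code{ENc = 2 + GC3s + 29 / (GC3s^2 + (1 - GC3s)^2)}. Genes lying on
#' the curve are compatible with pure mutation pressure; genes well below
#' it indicate selection on codon usage.
#'
#' @param gc3s Numeric vector of GC3s fractions in \code{[0, 1]}.
#' @return Expected ENc values.
#' @export
#' @examples
#' expectedENc(c(0, 0.5, 1))  # 31.0, 60.5, 32.0
expectedENc <- function(gc3s) {
  if (any(is.na(gc3s)) || any(gc3s < 0 | gc3s > 1))
    stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENc-GC3s analysis
#'
#' Places each gene relative to the expected ENc curve and classifies its
#' bias strength: strong (ENc <= 35), weak (50 <= ENc <= 61), intermediate
#' otherwise. The \code{position} relative to the curve uses the residual
#' \code{expected - observed}: genes more than \code{tolerance} ENc units
#' under the curve are \code{"below"}.
#'
#' @param profiles Data frame with columns \code{gene_id}, \code{enc},
#'   \code{gc3s} (e.g. from \code{\link{cubProfile}}).
#' @param tolerance Half-width (ENc units) of the "on the curve" band.
#' @return List with \code{points} (per-gene data frame adding
#'   \code{enc_expected}, \code{residual}, \code{position},
#'   \code{bias_class}) and \code{summary} (counts \code{n_strong},
#'   \code{n_intermediate}, \code{n_weak}, \code{pct_weak},
#'   \code{n_below_curve}, \code{n_defined}).
#' @export
encGc3sAnalysis <- function(profiles, tolerance = 0.5) {
  stopifnot(all(c("gene_id", "enc", "gc3s") %in% names(profiles)))
  ok <- !is.na(profiles$enc) & !is.na(profiles$gc3s)
  pts <- profiles[c("gene_id", "enc", "gc3s")]
  pts$enc_expected <- NA_real_
  pts$enc_expected[ok] <- expectedENc(pts$gc3s[ok])
  pts$residual <- pts$enc_expected - pts$enc
  pts$position <- ifelse(is.na(pts$residual), NA_character_,
                    ifelse(pts$residual > tolerance, "below",
                      ifelse(pts$residual < -tolerance, "above", "on")))
  pts$bias_class <- ifelse(is.na(pts$enc), NA_character_,
                      ifelse(pts$enc <= 35, "strong",
                        ifelse(pts$enc >= 50, "weak", "intermediate")))
  nDefined <- sum(ok)
  nStrong <- sum(pts$bias_class == "strong", na.rm = TRUE)
  nWeak <- sum(pts$bias_class == "weak", na.rm = TRUE)
  list(points = pts,
       summary = list(
         n_defined = nDefined,
         n_strong = nStrong,
         n_intermediate = nDefined - nStrong - nWeak,
         n_weak = nWeak,
         pct_weak = 100 * nWeak / nrow(profiles),
         n_below_curve = sum(pts$position == "below", na.rm = TRUE)))
}

#' Parity rule 2 (PR2) bias coordinates
#'
#' Third-position base parity within genes: under mutation-drift
#' equilibrium with no strand bias, A = T and G = C at silent third
#' positions, putting genes at the plot center (0.5, 0.5). Coordinates are
#' \code{x = G3 / (G3 + C3)} and \code{y = A3 / (A3 + T3)} over the third
#' positions of synonymous codons (default) or of fourfold-degenerate
#' families only (the classic formulation).
#'
#' @param object A \linkS4class{CodonCounts}.
#' @param scope \code{"all_synonymous"} (default) or \code{"fourfold_only"}.
#' @return Data frame with \code{gene_id}, \code{x}, \code{y} and
#'   \code{quadrant} relative to (0.5, 0.5); genes with a zero denominator
#'   get \code{NA} coordinates.
#' @export
pr2 <- function(object, scope = c("all_synonymous", "fourfold_only")) {
  scope <- match.arg(scope)
  stopifnot(is(object, "CodonCounts"))
  cods <- INFORMATIVE_CODONS
  if (scope == "fourfold_only")
    cods <- cods[FAMILY_SIZE[cods] == 4L]
  m <- counts(object)[, cods, drop = FALSE]
  p3 <- substr(cods, 3, 3)
  b3 <- sapply(BASES, function(b)
    rowSums(m[, p3 == b, drop = FALSE]))
  b3 <- matrix(b3, nrow = nrow(m), dimnames = list(rownames(m), BASES))
  x <- ifelse(b3[, "G"] + b3[, "C"] > 0,
              b3[, "G"] / (b3[, "G"] + b3[, "C"]), NA_real_)
  y <- ifelse(b3[, "A"] + b3[, "T"] > 0,
              b3[, "A"] / (b3[, "A"] + b3[, "T"]), NA_real_)
  quadrant <- ifelse(is.na(x) | is.na(y), NA_character_,
                paste0(ifelse(y >= 0.5, "A", "T"),
                       ifelse(x >= 0.5, "G", "C")))
  data.frame(gene_id = rownames(m), x = unname(x), y = unname(y),
             quadrant = unname(quadrant), stringsAsFactors = FALSE)
}

.regressionResult <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("zero variance in the predictor")
  fit <- lm(y ~ x)
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       pearson_r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Neutrality regression (GC12 on GC3)
#'
#' Ordinary least squares of GC12 (mean of the first two codon positions)
#' on GC3 across genes. A slope near 1 indicates that all three positions
#' drift together (mutation pressure dominates); a slope near 0 indicates
#' that third positions vary while the first two are constrained
#' (selection dominates). The slope is read as the fractional contribution
#' of mutation pressure.
#'
#' @param profiles Data frame with columns \code{gc12} and \code{gc3}.
#' @return List of class \code{"cubRegression"}: \code{slope},
#'   \code{intercept}, \code{pearson_r}, \code{p_value}, \code{n},
#'   \code{mutation_pct}, \code{selection_pct}.
#' @export
neutralityRegression <- function(profiles) {
  stopifnot(all(c("gc12", "gc3") %in% names(profiles)))
  res <- .regressionResult(profiles$gc3, profiles$gc12)
  res$mutation_pct <- res$slope * 100
  res$selection_pct <- (1 - res$slope) * 100
  structure(res, class = "cubRegression")
}

#' @export
print.cubRegression <- function(x, ...) {
  cat(sprintf(
    "slope %.4f, intercept %.4f, r %.3f, p %.3g, n %d\n",
    x$slope, x$intercept, x$pearson_r, x$p_value, x$n))
  if (!is.null(x$mutation_pct))
    cat(sprintf("mutation %.2f%% / selection %.2f%%\n",
                x$mutation_pct, x$selection_pct))
  invisible(x)
}

.starsFor <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
      ifelse(p < 0.05, "*", ""))))
}

#' Pairwise Pearson correlation matrix of CUB indices
#'
#' Pairwise Pearson correlations between the chosen index columns, with
#' two-sided p-values and significance stars (* p < 0.05, ** p < 0.01,
#' *** p < 0.001). Constant columns yield \code{NA} cells.
#'
#' @param profiles Data frame of per-gene indices.
#' @param indices Column names to correlate.
#' @return List of class \code{"cubCorrelationMatrix"} with symmetric
#'   matrices \code{r}, \code{p} and character matrix \code{stars}.
#' @export
correlationMatrix <- function(profiles, indices) {
  stopifnot(all(indices %in% names(profiles)), length(indices) >= 2L)
  m <- as.matrix(profiles[indices])
  stopifnot(is.numeric(m), nrow(m) >= 3L)
  k <- length(indices)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(indices, indices))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- m[, i]; xj <- m[, j]
    ok <- complete.cases(xi, xj)
    if (sum(ok) >= 3L && stats::sd(xi[ok]) > 0 && stats::sd(xj[ok]) > 0) {
      ct <- suppressWarnings(cor.test(xi[ok], xj[ok]))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix(.starsFor(p), k, k, dimnames = dimnames(p))
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars),
            class = "cubCorrelationMatrix")
}

#' @export
print.cubCorrelationMatrix <- function(x, digits = 3, ...) {
  out <- matrix(paste0(format(round(x$r, digits)), x$stars),
                nrow(x$r), dimnames = dimnames(x$r))
  out[is.na(x$r)] <- "NA"
  print(out, quote = FALSE)
  invisible(x)
}

#' ENc-expression correlation
#'
#' Relates codon bias to expression level: per condition, Pearson
#' correlation and OLS regression of expression (FPKM) on ENc. A
#' \code{"total"} condition — the per-gene sum over all conditions — is
#' appended. Highly expressed genes are expected to show lower ENc
#' (stronger bias), i.e. a negative relationship. Genes missing from the
#' expression table are dropped pairwise.
#'
#' @param profiles Data frame with \code{gene_id} and \code{enc}.
#' @param expression Long data frame with columns \code{gene_id},
#'   \code{condition}, \code{fpkm}.
#' @return Data frame, one row per condition (plus \code{"total"}):
#'   \code{condition}, \code{slope}, \code{intercept}, \code{pearson_r},
#'   \code{p_value}, \code{n}.
#' @export
expressionCorrelation <- function(profiles, expression) {
  stopifnot(all(c("gene_id", "enc") %in% names(profiles)),
            all(c("gene_id", "condition", "fpkm") %in% names(expression)))
  totals <- stats::aggregate(fpkm ~ gene_id, expression, sum)
  totals$condition <- "total"
  expr <- rbind(expression[c("gene_id", "condition", "fpkm")],
                totals[c("gene_id", "condition", "fpkm")])
  encByGene <- setNames(profiles$enc, profiles$gene_id)
  conds <- unique(expr$condition)
  do.call(rbind, lapply(conds, function(cond) {
    sub <- expr[expr$condition == cond, ]
    res <- .regressionResult(unname(encByGene[sub$gene_id]), sub$fpkm)
    data.frame(condition = cond, slope = res$slope,
               intercept = res$intercept, pearson_r = res$pearson_r,
               p_value = res$p_value, n = res$n,
               stringsAsFactors = FALSE)
  }))
}
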