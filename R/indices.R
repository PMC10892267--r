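# The core codon usage bias indices: RSCU, Wright's ENc, CAI, CBI, Fop.

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon c is its observed count divided by the count expected
#' under uniform usage within its synonymous family:
#' \code{RSCU(c) = observed(c) * family_size / family_total}. Values are
#' reported for the 59 informative codons (stops, ATG and TGG excluded).
#' Families with zero observations in a gene yield \code{NA}, never 0.
#'
#' @param object A \linkS4class{CodonCounts}.
#' @return Numeric matrix, genes x 59 codons. Within each observed family
#'   the values sum to the family size.
#' @export
#' @examples
#' cc <- codonCounts(c(g = "ATGAAAAAAAAAAAGTGA"))  # Lys AAA:3, AAG:1
#' rscu(cc)[, c("AAA", "AAG")]                     # 1.5, 0.5
rscu <- function(object) {
  stopifnot(is(object, "CodonCounts"))
  m <- counts(object)[, INFORMATIVE_CODONS, drop = FALSE]
  aa <- AA_OF[INFORMATIVE_CODONS]
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (a in unique(aa)) {
    cols <- which(aa == a)
    tot <- rowSums(m[, cols, drop = FALSE])
    k <- length(cols)
    vals <- m[, cols, drop = FALSE] * k / tot  # NaN-safe via tot>0 mask
    vals[tot == 0, ] <- NA_real_
    out[, cols] <- vals
  }
  out
}

#' Wright's effective number of codons (ENc)
#'
#' Per synonymous family with total count n >= 2, the codon homozygosity is
#' \code{F = (n * sum(p_i^2) - 1) / (n - 1)}. Family F values are averaged
#' within degeneracy classes (2-, 3-, 4-, 6-fold) and combined as
#' \code{ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6}, capped at 61. ENc ranges
#' from 20 (one codon per amino acid) to 61 (uniform usage).
#'
#' Families observed fewer than twice are excluded from their class mean.
#' If the single 3-fold family (Ile) is missing, \code{F3} is estimated as
#' the mean of \code{F2} and \code{F4}; if any other class has no usable
#' family, or a class mean is zero, ENc is undefined (\code{NA}).
#'
#' @param object A \linkS4class{CodonCounts}.
#' @return Numeric vector of ENc values, one per gene.
#' @export
enc <- function(object) {
  stopifnot(is(object, "CodonCounts"))
  m <- counts(object)[, SENSE_CODONS, drop = FALSE]
  aa <- AA_OF[SENSE_CODONS]
  degAA <- names(FAMILY_SIZE_BY_AA)[FAMILY_SIZE_BY_AA >= 2L]

  vapply(seq_len(nrow(m)), function(i) {
    Fv <- rep(NA_real_, length(degAA)); names(Fv) <- degAA
    for (a in degAA) {
      x <- m[i, aa == a]
      n <- sum(x)
      if (n >= 2) {
        p <- x / n
        Fv[a] <- (n * sum(p^2) - 1) / (n - 1)
      }
    }
    k <- FAMILY_SIZE_BY_AA[degAA]
    Fbar <- vapply(c(2, 3, 4, 6), function(kk) {
      v <- Fv[k == kk]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    names(Fbar) <- c("F2", "F3", "F4", "F6")
    if (is.na(Fbar["F3"]) && !is.na(Fbar["F2"]) && !is.na(Fbar["F4"]))
      Fbar["F3"] <- mean(Fbar[c("F2", "F4")])
    if (anyNA(Fbar) || any(Fbar <= 0)) return(NA_real_)
    min(2 + 9 / Fbar["F2"] + 1 / Fbar["F3"] +
          5 / Fbar["F4"] + 3 / Fbar["F6"], 61)
  }, numeric(1)) |> setNames(rownames(m))
}

#' Relative adaptiveness weights for CAI/Fop/CBI
#'
#' Holds per-codon relative adaptiveness \code{w} in \code{(0, 1]} derived
#' from a reference gene pool, and the optimal codon (w = 1) of each
#' degenerate family.
#'
#' @slot label Character label of the reference set.
#' @slot w Named numeric vector over the 59 informative codons.
#' @slot optimal Character vector: one optimal codon per degenerate family.
#' @export
setClass("ReferenceWeights",
  representation(label = "character", w = "numeric", optimal = "character"))

setValidity("ReferenceWeights", function(object) {
  msg <- character(0)
  if (!identical(names(object@w), INFORMATIVE_CODONS))
    msg <- c(msg, "w must be named by the 59 informative codons")
  ok <- is.na(object@w) | (object@w > 0 & object@w <= 1)
  if (!all(ok)) msg <- c(msg, "weights must lie in (0, 1]")
  fams <- AA_OF[object@optimal]
  if (anyDuplicated(fams))
    msg <- c(msg, "at most one optimal codon per family")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceWeights", function(object) {
  cat("ReferenceWeights '", object@label, "': ",
      length(object@optimal), " optimal codons\n", sep = "")
})

#' @describeIn ReferenceWeights-class The optimal codon set (w = 1).
#' @param object A \code{ReferenceWeights}.
#' @export
setGeneric("optimalSet", function(object) standardGeneric("optimalSet"))

#' @export
setMethod("optimalSet", "ReferenceWeights", function(object) object@optimal)

#' @describeIn ReferenceWeights-class The weight vector.
#' @export
setGeneric("weights59", function(object) standardGeneric("weights59"))

#' @export
setMethod("weights59", "ReferenceWeights", function(object) object@w)

#' Derive reference weights from a gene pool
#'
#' Computes relative adaptiveness \code{w = RSCU / max(RSCU)} within each
#' family from a pooled codon count table (typically a high-expression
#' reference pool). Codons absent from the reference receive a small floor
#' weight (\code{wFloor}, default 0.01) so that CAI stays defined; ties for
#' the family maximum are broken lexicographically when naming the optimal
#' codon.
#'
#' @param pool A single-row \linkS4class{CodonCounts} (see
#'   \code{\link{poolCounts}}).
#' @param label Label for the reference set.
#' @param wFloor Weight assigned to reference-absent codons.
#' @return A \linkS4class{ReferenceWeights}.
#' @export
referenceWeights <- function(pool, label = "reference", wFloor = 0.01) {
  stopifnot(is(pool, "CodonCounts"), nrow(counts(pool)) == 1L)
  r <- rscu(pool)[1, ]
  w <- rep(NA_real_, length(INFORMATIVE_CODONS))
  names(w) <- INFORMATIVE_CODONS
  optimal <- character(0)
  aa <- AA_OF[INFORMATIVE_CODONS]
  for (a in unique(aa)) {
    cols <- INFORMATIVE_CODONS[aa == a]
    v <- r[cols]
    if (all(is.na(v))) next  # family absent: weights stay NA
    wf <- v / max(v)
    wf[is.na(wf) | wf <= 0] <- wFloor
    w[cols] <- wf
    optimal <- c(optimal, cols[which.max(v == max(v))][1])
  }
  new("ReferenceWeights", label = label, w = w,
      optimal = sort(optimal))
}

.checkRefCoverage <- function(m, ref) {
  w <- weights59(ref)
  used <- colSums(m) > 0
  if (anyNA(w[used]))
    stop("reference weights missing for family of codon(s): ",
         paste(names(w)[used & is.na(w)], collapse = ", "))
}

#' Codon adaptation index (CAI)
#'
#' Sharp-Li CAI: the geometric mean of relative adaptiveness weights over
#' all codons of degenerate families (Met, Trp and stops excluded).
#'
#' @param object A \linkS4class{CodonCounts}.
#' @param ref A \linkS4class{ReferenceWeights}.
#' @return Numeric vector of CAI values in \code{(0, 1]}.
#' @export
cai <- function(object, ref) {
  stopifnot(is(object, "CodonCounts"), is(ref, "ReferenceWeights"))
  m <- counts(object)[, INFORMATIVE_CODONS, drop = FALSE]
  .checkRefCoverage(m, ref)
  lw <- log(weights59(ref))
  lw[is.na(lw)] <- 0  # absent families never hit: coverage checked above
  tot <- rowSums(m)
  if (any(tot == 0)) stop("no codons from degenerate families")
  exp(as.vector(m %*% lw) / tot) |> setNames(rownames(m))
}

#' Frequency of optimal codons (Fop)
#'
#' Fraction of codons from degenerate families that are optimal under the
#' reference set.
#'
#' @inheritParams cai
#' @return Numeric vector in \code{[0, 1]}.
#' @export
fop <- function(object, ref) {
  stopifnot(is(object, "CodonCounts"), is(ref, "ReferenceWeights"))
  m <- counts(object)[, INFORMATIVE_CODONS, drop = FALSE]
  tot <- rowSums(m)
  if (any(tot == 0)) stop("no synonymous codons")
  nOpt <- rowSums(m[, intersect(colnames(m), optimalSet(ref)),
                    drop = FALSE])
  (nOpt / tot) |> setNames(rownames(m))
}

#' Codon bias index (CBI)
#'
#' Bennetzen-Hall CBI: \code{(Nopt - Nrand) / (Ntot - Nrand)}, where
#' \code{Nrand} is the optimal-codon count expected under uniform usage
#' within each family. 1 means exclusively optimal codons, 0 random usage,
#' negative values anti-optimal usage.
#'
#' @inheritParams cai
#' @return Numeric vector in \code{[-1, 1]}; \code{NA} when the
#'   denominator degenerates.
#' @export
cbi <- function(object, ref) {
  stopifnot(is(object, "CodonCounts"), is(ref, "ReferenceWeights"))
  m <- counts(object)[, INFORMATIVE_CODONS, drop = FALSE]
  opt <- optimalSet(ref)
  aa <- AA_OF[INFORMATIVE_CODONS]
  nTot <- rowSums(m)
  nOpt <- rowSums(m[, intersect(colnames(m), opt), drop = FALSE])
  # expected optimal count: per family, n_family * (#optimal in family)/size
  perFamOptFrac <- vapply(INFORMATIVE_CODONS, function(cod) {
    famCodons <- FAMILIES[[AA_OF[cod]]]
    sum(famCodons %in% opt) / length(famCodons)
  }, numeric(1))
  nRand <- as.vector(m %*% perFamOptFrac)
  out <- ifelse(abs(nTot - nRand) < .Machine$double.eps^0.5, NA_real_,
                (nOpt - nRand) / (nTot - nRand))
  setNames(out, rownames(m))
}

#' High-frequency codons
#'
#' Codons with RSCU strictly greater than 1 (codons with RSCU equal to 1
#' are removed from consideration).
#'
#' @param rscuValues A named RSCU vector, or a single-row matrix from
#'   \code{\link{rscu}}.
#' @return Character vector of codons.
#' @export
highFrequencyCodons <- function(rscuValues) {
  if (is.matrix(rscuValues)) {
    stopifnot(nrow(rscuValues) == 1L)
    rscuValues <- rscuValues[1, ]
  }
  sort(names(rscuValues)[!is.na(rscuValues) & rscuValues > 1])
}
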