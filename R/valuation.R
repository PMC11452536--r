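#' @include AllClasses.R AllGenerics.R expression-models.R evaluation.R
NULL

# ---------------------------------------------------------------------------
# Value function
# ---------------------------------------------------------------------------

#' Precompute per-slide training statistics for subset valuation
#'
#' Featurizes each slide once and caches the ridge sufficient statistics
#' (X'X, X'y on log1p targets), so that any training-subset fit reduces to
#' summing statistics and solving a small linear system. Share the result
#' across value functions for different validation slides.
#'
#' @param slides named list of training [Slide-class] objects.
#' @param spec a [predictorSpec()] list.
#' @return named list of per-slide statistics.
#' @export
precomputeSlideFeatures <- function(slides, spec = predictorSpec()) {
  if (is.null(names(slides))) {
    names(slides) <- vapply(slides, slideId, character(1))
  }
  pspec <- patchSpec(spec$patchPx, stridePx = spec$patchPx)
  lapply(slides, function(s) {
    X <- cbind(`(Intercept)` = 1, featurizeSlide(s, pspec))
    Y <- makeTargets(s)@continuous
    list(XtX = crossprod(X), XtY = crossprod(X, Y), n = nrow(X),
         X = X, geneIds = colnames(Y))
  })
}

#' Build the coalition value function V(S)
#'
#' `V(S)` is the macro AUC on the validation slide of per-gene continuous
#' (ridge) predictors trained on the slides in S; validation labels are
#' the slide's median-dichotomized expression and predictions are scored
#' as the ranking statistic (AUC is rank-based, so the continuous head's
#' predictions are a valid score). The empty coalition returns `vEmpty`
#' (default 0.5, chance-level AUC). Values are memoized per subset; a
#' subset whose training fails falls back to `vEmpty` with a warning flag
#' recorded in the memo.
#'
#' @param trainSlides named list of training [Slide-class] objects.
#' @param valSlide the validation [Slide-class].
#' @param geneIds genes to score (default: all genes of the validation
#'   slide).
#' @param spec a [predictorSpec()] list; `lambdaGrid[1]` is not used here
#'   — the subset fits use the fixed penalty `lambda`.
#' @param lambda ridge penalty for subset fits.
#' @param vEmpty empty-coalition value.
#' @param stats optional [precomputeSlideFeatures()] output to share
#'   across value functions.
#' @return a [ValueFunction-class].
#' @export
makeValueFunction <- function(trainSlides, valSlide, geneIds = NULL,
                              spec = predictorSpec(), lambda = 1e-3,
                              vEmpty = 0.5, stats = NULL) {
  if (is.null(names(trainSlides))) {
    names(trainSlides) <- vapply(trainSlides, slideId, character(1))
  }
  if (is.null(stats)) stats <- precomputeSlideFeatures(trainSlides, spec)
  if (is.null(geneIds)) geneIds <- rownames(valSlide)
  pspec <- patchSpec(spec$patchPx, stridePx = spec$patchPx)
  Xval <- cbind(1, featurizeSlide(valSlide, pspec))
  valBin <- makeTargets(valSlide, geneIds)@binary
  okGene <- colnames(valBin)[apply(valBin, 2,
                                   function(y) length(unique(y)) == 2L)]
  memo <- new.env(parent = emptyenv())
  p <- nrow(stats[[1]]$XtX)
  fn <- function(subset) {
    if (!length(subset)) return(vEmpty)
    st <- stats[subset]
    XtX <- Reduce(`+`, lapply(st, `[[`, "XtX"))
    XtY <- Reduce(`+`, lapply(st, function(s) s$XtY[, geneIds, drop = FALSE]))
    n <- sum(vapply(st, `[[`, numeric(1), "n"))
    B <- tryCatch(.ridgeSolve(XtX, XtY, n, lambda),
                  error = function(e) NULL)
    if (is.null(B)) {
      assign(paste0("failed:", paste(sort(subset), collapse = "+")), TRUE,
             envir = memo)
      warning("training failed on a subset; using the empty-set value")
      return(vEmpty)
    }
    scores <- Xval %*% B
    colnames(scores) <- geneIds
    auc <- vapply(okGene, function(g) {
      suppressWarnings(aucScore(valBin[, g], scores[, g]))
    }, numeric(1))
    mean(auc, na.rm = TRUE)
  }
  new("ValueFunction", slideIds = names(trainSlides), fn = fn,
      vEmpty = vEmpty, memo = memo,
      meta = list(validationSlide = slideId(valSlide), metric = "macro_auc",
                  lambda = lambda, predictorSpec = spec,
                  genes = geneIds))
}

#' Wrap an arbitrary subset-value function
#'
#' Utility for tests and for plugging in alternative training procedures:
#' any function from a character subset to a numeric value becomes a
#' memoized [ValueFunction-class].
#'
#' @param slideIds player identifiers.
#' @param fn function(character subset) -> numeric value.
#' @param vEmpty empty-coalition value.
#' @return a [ValueFunction-class].
#' @export
valueFunction <- function(slideIds, fn, vEmpty = 0.5) {
  new("ValueFunction", slideIds = slideIds, fn = fn, vEmpty = vEmpty,
      memo = new.env(parent = emptyenv()), meta = list())
}

#' @describeIn valueFunction memoized evaluation of V on a subset.
#' @param valueFn a [ValueFunction-class].
#' @param subset character vector of slide ids.
#' @export
setMethod("evaluateSubset", "ValueFunction", function(valueFn, subset) {
  subset <- as.character(subset)
  if (!all(subset %in% valueFn@slideIds)) {
    stop("subset contains unknown slide ids", call. = FALSE)
  }
  if (!length(subset)) return(valueFn@vEmpty)
  key <- paste(sort(subset), collapse = "+")
  if (!is.null(v <- valueFn@memo[[key]])) return(v)
  v <- valueFn@fn(subset)
  assign(key, v, envir = valueFn@memo)
  v
})

# ---------------------------------------------------------------------------
# Shapley estimation
# ---------------------------------------------------------------------------

#' Exact data-Shapley values
#'
#' The Shapley value of slide i is its marginal contribution
#' `V(S + i) - V(S)` averaged over all orderings; computed here through
#' the equivalent subset-weighted form
#' `phi_i = sum over S not containing i of |S|! (n-1-|S|)! / n! *
#' (V(S+i) - V(S))`
#' with all `2^n` coalition values memoized. Efficiency
#' `sum phi_i = V(full) - V(empty)` holds by construction.
#'
#' @param valueFn a [ValueFunction-class].
#' @param maxSlides guard on the player count (default 10).
#' @return a [ShapleyEstimate-class] with `method = "exact"`.
#' @export
shapleyExact <- function(valueFn, maxSlides = 10L) {
  ids <- valueFn@slideIds
  n <- length(ids)
  if (n > maxSlides) {
    stop(sprintf("exact Shapley over %d slides needs 2^%d evaluations; %s",
                 n, n, "use shapleyMonteCarlo"), call. = FALSE)
  }
  nSub <- 2^n
  values <- numeric(nSub)
  sizes <- integer(nSub)
  for (m in seq_len(nSub) - 1L) {
    members <- ids[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
    sizes[m + 1L] <- length(members)
    values[m + 1L] <- evaluateSubset(valueFn, members)
  }
  wt <- factorial(0:(n - 1)) * factorial((n - 1):0) / factorial(n)
  phi <- stats::setNames(numeric(n), ids)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (m in seq_len(nSub) - 1L) {
      if (bitwAnd(m, bit) == 0L) {
        s <- sizes[m + 1L]
        phi[i] <- phi[i] + wt[s + 1L] *
          (values[bitwOr(m, bit) + 1L] - values[m + 1L])
      }
    }
  }
  new("ShapleyEstimate", phi = phi, se = stats::setNames(numeric(n), ids),
      nPermutations = NA_integer_, converged = TRUE, method = "exact",
      vEmpty = valueFn@vEmpty, vFull = values[nSub])
}

#' Monte Carlo data-Shapley values
#'
#' Averages marginal contributions over uniformly sampled permutations of
#' the training slides, reporting per-slide running means and Monte Carlo
#' standard errors. Optional truncation (as in truncated Monte Carlo
#' Shapley): within a permutation, once the prefix value is within
#' `truncationTol` of the full-coalition value, the remaining marginals
#' are set to 0.
#'
#' @param valueFn a [ValueFunction-class].
#' @param nPermutations sampled permutations (>= 1; default 200).
#' @param seed integer seed.
#' @param truncationTol nonnegative tolerance; `NULL` (default) disables
#'   truncation.
#' @return a [ShapleyEstimate-class] with `method = "monte_carlo"`.
#' @export
shapleyMonteCarlo <- function(valueFn, nPermutations = 200L, seed = 1L,
                              truncationTol = NULL) {
  nPermutations <- .assertCount(nPermutations, "nPermutations")
  ids <- valueFn@slideIds
  n <- length(ids)
  truncate <- !is.null(truncationTol)
  if (truncate && truncationTol < 0) {
    stop("truncationTol must be >= 0", call. = FALSE)
  }
  vFull <- evaluateSubset(valueFn, ids)
  marg <- matrix(0, nPermutations, n, dimnames = list(NULL, ids))
  perms <- .withSeed(seed, {
    lapply(seq_len(nPermutations), function(b) sample(ids))
  })
  for (b in seq_len(nPermutations)) {
    pi <- perms[[b]]
    prev <- valueFn@vEmpty
    prefix <- character(0)
    for (j in seq_len(n)) {
      if (truncate && abs(prev - vFull) <= truncationTol) {
        # remaining marginals in this permutation are truncated to 0
        break
      }
      prefix <- c(prefix, pi[j])
      cur <- evaluateSubset(valueFn, prefix)
      marg[b, pi[j]] <- cur - prev
      prev <- cur
    }
  }
  phi <- colMeans(marg)
  se <- stats::setNames(apply(marg, 2, stats::sd) / sqrt(nPermutations), ids)
  se[is.na(se)] <- 0
  new("ShapleyEstimate", phi = phi, se = se,
      nPermutations = nPermutations,
      converged = all(is.finite(phi)), method = "monte_carlo",
      vEmpty = valueFn@vEmpty, vFull = vFull)
}

#' @rdname shapleyValues
setMethod("shapleyValues", "ShapleyEstimate", function(x) x@phi)

setMethod("show", "ShapleyEstimate", function(object) {
  cat(sprintf("ShapleyEstimate (%s): V(empty)=%.4f, V(full)=%.4f\n",
              object@method, object@vEmpty, object@vFull))
  for (i in seq_along(object@phi)) {
    cat(sprintf("  %-18s phi = %+.5f (se %.5f)\n",
                names(object@phi)[i], object@phi[i], object@se[i]))
  }
})

# ---------------------------------------------------------------------------
# Costs
# ---------------------------------------------------------------------------

#' Default synthetic cost model
#'
#' Placeholder per-slide costs (arbitrary currency units): manual staining
#' and per-slide handling make a traditional capture area dearer than an
#' enhanced one even though the enhanced area carries more spots, matching
#' the direction that enhanced slides amortize cost over two patients.
#'
#' @return a [CostModel-class].
#' @export
defaultCostModel <- function() {
  new("CostModel",
      baseCost = c(traditional = 1300, enhanced = 800),
      perSpot = 0.05,
      labor = c(traditional = 450, enhanced = 150),
      sequencing = c(traditional = 600, enhanced = 600),
      label = "synthetic-default-v1")
}

#' Per-slide assay cost
#'
#' `base(protocol) + perSpot * detected spots + labor(protocol) +
#' sequencing(protocol)`, itemized in the `components` attribute.
#'
#' @param slide a [Slide-class] (protocol and spot count are read from
#'   it), or a list with `protocol` name and `nSpots`.
#' @param model a [CostModel-class].
#' @return numeric total cost with attribute `components`.
#' @export
slideCost <- function(slide, model = defaultCostModel()) {
  if (is(slide, "Slide")) {
    proto <- protocol(slide)@name
    ns <- nSpots(slide)
  } else {
    proto <- slide$protocol
    ns <- slide$nSpots
  }
  comp <- c(base = unname(model@baseCost[proto]),
            spots = model@perSpot * ns,
            labor = unname(model@labor[proto]),
            sequencing = unname(model@sequencing[proto]))
  structure(sum(comp), components = comp, costModel = model@label)
}

setMethod("show", "CostModel", function(object) {
  cat(sprintf("CostModel '%s': base %s; %.3g per spot; labor %s; sequencing %s\n",
              object@label,
              paste(sprintf("%s=%.0f", names(object@baseCost),
                            object@baseCost), collapse = "/"),
              object@perSpot,
              paste(sprintf("%s=%.0f", names(object@labor), object@labor),
                    collapse = "/"),
              paste(sprintf("%s=%.0f", names(object@sequencing),
                            object@sequencing), collapse = "/")))
})

# ---------------------------------------------------------------------------
# Group comparisons
# ---------------------------------------------------------------------------

#' Mann-Whitney comparison of two groups with rank-biserial effect size
#'
#' Returns the U statistic of the first group over the second, the
#' rank-biserial correlation `r = 1 - 2U / (n1 * n2)`, and the two-sided
#' p-value (exact for tie-free small groups). Sign convention: positive
#' `r` means the second-named group tends to take larger values (complete
#' separation with the first group entirely below the second gives
#' `r = 1`); this convention is carried in the `convention` field of the
#' output.
#'
#' @param x,y numeric samples (first and second group).
#' @return list with `U`, `rankBiserial`, `p`, `exact`, `n1`, `n2`,
#'   `convention`.
#' @export
compareGroups <- function(x, y) {
  mw <- mannWhitneyU(x, y)
  n1 <- length(x); n2 <- length(y)
  list(U = mw$U, rankBiserial = 1 - 2 * mw$U / (n1 * n2), p = mw$p,
       exact = mw$exact, n1 = n1, n2 = n2,
       convention = "positive rank-biserial: second group tends larger")
}

#' Protocol comparisons of a valuation table
#'
#' The four comparisons of the study design, each contrasting traditional
#' against enhanced training slides: (i) per-slide assay costs, (ii)
#' Shapley values on the enhanced validation slide, (iii) Shapley values
#' on the traditional validation slide, and (iv) Shapley-to-cost ratios on
#' each validation slide. Each row reports U (traditional over enhanced),
#' rank-biserial r, and the two-sided p (exact at these group sizes).
#'
#' @param table a per-slide valuation data.frame with columns `slide_id`,
#'   `protocol`, `validation`, `phi`, `cost`, `ratio`.
#' @return data.frame of comparisons.
#' @export
compareProtocols <- function(table) {
  stopifnot(all(c("slide_id", "protocol", "validation", "phi", "cost",
                  "ratio") %in% names(table)))
  rows <- list()
  addRow <- function(name, x, y) {
    cg <- compareGroups(x, y)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = name, U = cg$U, rank_biserial = cg$rankBiserial,
      p = cg$p, exact = cg$exact, n_traditional = cg$n1,
      n_enhanced = cg$n2)
  }
  costTab <- unique(table[, c("slide_id", "protocol", "cost")])
  addRow("cost", costTab$cost[costTab$protocol == "traditional"],
         costTab$cost[costTab$protocol == "enhanced"])
  for (v in unique(table$validation)) {
    sub <- table[table$validation == v, ]
    addRow(paste0("phi_on_", v),
           sub$phi[sub$protocol == "traditional"],
           sub$phi[sub$protocol == "enhanced"])
    addRow(paste0("ratio_on_", v),
           sub$ratio[sub$protocol == "traditional"],
           sub$ratio[sub$protocol == "enhanced"])
  }
  out <- do.call(rbind, rows)
  attr(out, "convention") <-
    "U counts traditional-over-enhanced wins; positive rank-biserial: enhanced tends larger"
  out
}

# ---------------------------------------------------------------------------
# Cohort valuation
# ---------------------------------------------------------------------------

#' Value every training slide of a cohort against both validation slides
#'
#' Builds one value function per validation slide over shared per-slide
#' training statistics, estimates per-slide Shapley values (exact by
#' default; Monte Carlo above `exactMax` slides), attaches per-slide costs
#' and Shapley-to-cost ratios, and runs the protocol comparisons.
#'
#' @param cohort a [Cohort-class].
#' @param spec a [predictorSpec()] list.
#' @param costModel a [CostModel-class].
#' @param method `"exact"` or `"monte_carlo"`.
#' @param nPermutations Monte Carlo permutations when used.
#' @param seed integer seed.
#' @param lambda ridge penalty of the value function.
#' @param vEmpty empty-coalition value (chance AUC).
#' @return a [ValuationResult-class].
#' @export
valuateCohort <- function(cohort, spec = predictorSpec(),
                          costModel = defaultCostModel(),
                          method = c("exact", "monte_carlo"),
                          nPermutations = 200L, seed = 1L,
                          lambda = 1e-3, vEmpty = 0.5) {
  method <- match.arg(method)
  train <- cohortSlides(cohort, "train")
  vals <- cohortSlides(cohort, "validation")
  stopifnot(length(train) >= 1L, length(vals) >= 1L)
  stats <- precomputeSlideFeatures(train, spec)
  design <- cohortDesign(cohort)
  protoOf <- stats::setNames(design$protocol, design$slide_id)
  estimates <- list()
  rows <- list()
  for (vid in names(vals)) {
    vf <- makeValueFunction(train, vals[[vid]], spec = spec,
                            lambda = lambda, vEmpty = vEmpty,
                            stats = stats)
    est <- if (method == "exact") {
      shapleyExact(vf)
    } else {
      shapleyMonteCarlo(vf, nPermutations = nPermutations,
                        seed = .childSeed(seed, .stringSeed(vid) %% 1000L))
    }
    estimates[[vid]] <- est
    cost <- vapply(train, slideCost, numeric(1), model = costModel)
    rows[[vid]] <- data.frame(
      slide_id = names(train),
      protocol = unname(protoOf[names(train)]),
      validation = protoOf[[vid]],
      phi = unname(est@phi[names(train)]),
      se = unname(est@se[names(train)]),
      cost = unname(cost),
      ratio = unname(est@phi[names(train)] / cost),
      row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("ValuationResult", table = tab, estimates = estimates,
      costModel = costModel, comparisons = compareProtocols(tab))
}

#' @rdname shapleyValues
setMethod("shapleyValues", "ValuationResult", function(x) {
  stats::setNames(x@table$phi, paste(x@table$slide_id, x@table$validation,
                                     sep = "@"))
})

setMethod("show", "ValuationResult", function(object) {
  cat(sprintf("ValuationResult: %d slide-validation pairs (cost model '%s')\n",
              nrow(object@table), object@costModel@label))
  print(object@table, digits = 4)
  cat("Comparisons (U: traditional over enhanced):\n")
  print(object@comparisons, digits = 4)
})
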