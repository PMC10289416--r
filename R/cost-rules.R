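COST_BANDS <- c("46-49", "50-54", "55-59", "60-64", "65-69", "70-74", "75+")
COST_BAND_STARTS <- c(46, 50, 55, 60, 65, 70, 75)

#' Treatment and screening cost model
#'
#' Treatment costs are organised in three phase tables by 5-year age band
#' (age at diagnosis) and stage: \code{C1} the first year after diagnosis,
#' \code{C2} per year for years 2-5, and \code{C3} the last year before a
#' breast cancer death. All values are euros; screening costs a flat
#' \code{screening_unit_cost} euros per invitee per screened round.
#'
#' @param C1,C2,C3 numeric \code{7 x 5} matrices (rows: age bands 46-49,
#'   50-54, 55-59, 60-64, 65-69, 70-74, 75+; columns: stages 0-4).
#' @param screening_unit_cost euros per invitee (default 30).
#' @return an object of class \code{cost_model}.
#' @export
cost_model <- function(C1, C2, C3, screening_unit_cost = 30) {
  fix <- function(m, nm) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(7L, 5L))) {
      stop(nm, " must be a 7 x 5 matrix (bands x stages)")
    }
    dimnames(m) <- list(COST_BANDS, DIAG_STAGE_LABELS)
    m
  }
  structure(list(C1 = fix(C1, "C1"), C2 = fix(C2, "C2"), C3 = fix(C3, "C3"),
                 screening_unit_cost = screening_unit_cost),
            class = "cost_model")
}

validate_cost_model <- function(cm) {
  bad <- character(0)
  if (!inherits(cm, "cost_model")) return("cost_model missing or wrong class")
  for (nm in c("C1", "C2", "C3")) {
    m <- cm[[nm]]
    if (anyNA(m)) bad <- c(bad, sprintf("cost_model: %s has missing cells", nm))
    if (any(m < 0, na.rm = TRUE)) {
      bad <- c(bad, sprintf("cost_model: %s has negative cells", nm))
    }
  }
  if (cm$screening_unit_cost < 0) {
    bad <- c(bad, "cost_model: negative screening unit cost")
  }
  bad
}

#' @export
print.cost_model <- function(x, ...) {
  cat("cost_model: 7 age bands x 5 stages, screening",
      x$screening_unit_cost, "euros/invitee\n")
  invisible(x)
}

#' Map a 2-year model age group onto its 5-year cost band
#'
#' Costs are indexed by age at diagnosis; group \code{j} (ages
#' \code{44+2j} to \code{45+2j}) is assigned the band containing its lower
#' age, with everything from 75 up pooled into \code{75+}.
#'
#' @param j age-group index (vectorised).
#' @param grid an \code{age_grid}.
#' @return band index 1..7 (named with the band label).
#' @export
band_of <- function(j, grid = age_grid()) {
  age <- lower_age(grid, j)
  if (any(age < COST_BAND_STARTS[1])) stop("age group below the cost bands")
  b <- findInterval(age, COST_BAND_STARTS)
  names(b) <- COST_BANDS[b]
  b
}

#' Accumulated treatment cost of one case
#'
#' A patient diagnosed at stage \code{k} in cost band \code{band} who dies
#' during the \code{n}-th year after diagnosis accrues, for an other-cause
#' death (\code{d = 2}):
#' \deqn{C_n = C_1 + (n-1) C_2 \;(1 \le n \le 5), \qquad C_1 + 4 C_2 \;(n > 5)}
#' and for a breast cancer death (\code{d = 1}):
#' \deqn{C_n = (n-1) C_1 + C_3 \;(n \in \{1,2\}), \quad
#'       C_1 + (n-2) C_2 + C_3 \;(n \in \{3,4,5\}), \quad
#'       C_1 + 4 C_2 + C_3 \;(n > 5).}
#' The \code{n = 2} breast cancer branch carries no \code{C2} term; the
#' rule is applied exactly as stated, not harmonised. Costs plateau beyond
#' year 5 (treatment is counted for at most five years).
#'
#' @param n years from diagnosis to death, inclusive count (\code{n >= 1});
#'   a survival time of \code{t} whole years maps to \code{n = t + 1}.
#' @param d cause of death: 1 breast cancer, 2 other.
#' @param band cost band index 1..7 (see \code{\link{band_of}}).
#' @param k stage 0..4.
#' @param cm a \code{cost_model}.
#' @return euros (vectorised over \code{n}, \code{d}, \code{band},
#'   \code{k}).
#' @export
accumulate_cost <- function(n, d, band, k, cm) {
  if (any(n < 1)) stop("cost year index n must be >= 1")
  if (!all(d %in% c(1, 2))) stop("cause d must be 1 (breast cancer) or 2")
  if (!all(k %in% 0:4)) stop("stage k must be in 0..4")
  len <- max(length(n), length(d), length(band), length(k))
  n <- rep_len(n, len); d <- rep_len(d, len)
  band <- rep_len(band, len); k <- rep_len(k, len)
  c1 <- cm$C1[cbind(band, k + 1L)]
  c2 <- cm$C2[cbind(band, k + 1L)]
  c3 <- cm$C3[cbind(band, k + 1L)]
  out <- numeric(len)
  oc <- d == 2
  out[oc] <- c1[oc] + pmin(n[oc] - 1, 4) * c2[oc]
  bc <- d == 1
  early <- bc & n <= 2
  out[early] <- (n[early] - 1) * c1[early] + c3[early]
  mid <- bc & n >= 3 & n <= 5
  out[mid] <- c1[mid] + (n[mid] - 2) * c2[mid] + c3[mid]
  late <- bc & n > 5
  out[late] <- c1[late] + 4 * c2[late] + c3[late]
  out
}

#' Dense treatment-cost tensor over (age group, stage, survival time, cause)
#'
#' Tabulates \code{C(j, k, t, d) = accumulate_cost(t + 1, d, band_of(j), k)}
#' for every diagnosed stage; the cancer-free state \code{k = -1} carries no
#' treatment cost and is not represented (treat it as 0).
#'
#' @param cm a \code{cost_model}.
#' @param grid an \code{age_grid}.
#' @param Tn number of survival-time points (\code{t = 0..Tn-1}).
#' @return numeric array \code{J x 5 x Tn x 2}.
#' @export
build_cost_tensor <- function(cm, grid, Tn) {
  J <- grid$J
  ct <- array(0, dim = c(J, 5L, Tn, 2L),
              dimnames = list(NULL, DIAG_STAGE_LABELS, NULL, c("d1", "d2")))
  bands <- band_of(seq_len(J), grid)
  tv <- seq_len(Tn) - 1L
  for (j in seq_len(J)) {
    for (k in 0:4) {
      for (d in 1:2) {
        ct[j, k + 1L, , d] <- accumulate_cost(tv + 1L, d, bands[j], k, cm)
      }
    }
  }
  ct
}

#' Scale all treatment-cost cells
#'
#' Multiplies every cell of \code{C1}, \code{C2}, \code{C3} by
#' \code{factor}; the screening unit cost is left untouched. Used by the
#' cost sensitivity scenarios (+10\%, +50\%).
#'
#' @param cm a \code{cost_model}.
#' @param factor positive multiplier.
#' @return a new \code{cost_model}.
#' @export
scale_treatment_costs <- function(cm, factor) {
  if (factor <= 0) stop("cost scale factor must be > 0")
  cost_model(cm$C1 * factor, cm$C2 * factor, cm$C3 * factor,
             screening_unit_cost = cm$screening_unit_cost)
}
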