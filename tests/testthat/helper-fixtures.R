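# Small hand-built fixtures with fully controlled probabilities, used where
# tests need exact closed-form answers rather than generated data.

# Degenerate fixture: configurable incidence, point-mass or simple survival
# laws. Survival support t = 0..Tn-1.
make_fixture <- function(J = 2L, iota_S = 0.01, iota_NS = 0.01,
                         q = c(0.1, 0.5, 0.25, 0.01, 0.14),
                         lam_free = NULL, lam_diag = NULL,
                         bc_share = 0.5, Tn = 6L,
                         screening_unit_cost = 30, N0 = 1e5) {
  grid <- age_grid(J)
  if (is.null(lam_free)) { # default: everyone survives >= 2 years
    lam_free <- c(rep(0, Tn - 1L), 1)
  }
  if (is.null(lam_diag)) lam_diag <- lam_free
  stopifnot(length(lam_free) == Tn, length(lam_diag) == Tn)
  incidence <- cbind(S = rep(iota_S, J), NS = rep(iota_NS, J))
  stages <- array(rep(q, each = J * 2L), dim = c(J, 2L, 5L),
                  dimnames = list(NULL, c("S", "NS"), paste0("k", 0:4)))
  survival <- array(0, dim = c(J, 6L, Tn),
                    dimnames = list(NULL,
                                    c("k-1", paste0("k", 0:4)), NULL))
  causes <- array(0, dim = c(J, 5L, Tn, 2L))
  for (j in seq_len(J)) {
    survival[j, 1L, ] <- lam_free
    for (ki in 2:6) survival[j, ki, ] <- lam_diag
    for (ki in 1:5) {
      causes[j, ki, , 1L] <- lam_diag * bc_share
      causes[j, ki, , 2L] <- lam_diag * (1 - bc_share)
    }
  }
  model_inputs(grid, incidence, stages, survival, causes,
               cost_model(matrix(0, 7, 5), matrix(0, 7, 5),
                          matrix(0, 7, 5),
                          screening_unit_cost = screening_unit_cost),
               N0 = N0)
}

paper_costs <- flexscreen::paper_fixture()$cost_model

all_S <- function(J) rep("S", J)
all_NS <- function(J) rep("NS", J)
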