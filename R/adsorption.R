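#' Solve the competitive Langmuir partition
#'
#' Splits, for each species, the total liquid-accessible amount
#' \code{M_i = C_S,i + C_F,i} (mg/L) between the free solution and the shared
#' cell-wall binding sites, under the competitive Langmuir isotherm
#' \deqn{C_{S,i} = Q_i K_i C_{F,i} / (1 + \sum_j K_j C_{F,j})}
#' with \code{Q_i} the per-litre surface capacity (mg/L).
#'
#' The N-species system is reduced to one scalar equation in the saturation
#' sum \code{S = sum(K_j * C_F,j)}: for a trial \code{S},
#' \code{C_F,i = M_i (1+S) / ((1+S) + Q_i K_i)}, and the fixed point of
#' \code{g(S) = sum(K_i C_F,i(S))} is bracketed in \code{[0, sum(K_i M_i)]}
#' where it is unique. The bracketing root is polished with Newton steps to
#' near machine precision.
#'
#' @param M Named or unnamed vector of total liquid-accessible amounts, mg/L.
#' @param K Langmuir equilibrium constants, L/mg (same length as \code{M}).
#' @param Q Surface capacities on the must-volume basis, mg/L
#'   (\code{Gamma * phi * grape_load * q_m}).
#' @param tol Relative tolerance on the saturation-sum root (default 1e-12).
#' @return Object of class \code{phx_partition}: list with \code{C_F},
#'   \code{C_S}, \code{S} and \code{residual} (worst violation of
#'   conservation or the isotherm relation, mg/L).
#' @export
#' @examples
#' solve_partition(M = 50, K = 0.01, Q = 100)  # C_F ~ 28.08, C_S ~ 21.92
solve_partition <- function(M, K, Q, tol = 1e-12) {
  n <- length(M)
  stopifnot(length(K) == n, length(Q) == n)
  if (any(!is.finite(M)) || any(!is.finite(K)) || any(!is.finite(Q))) {
    stop("validation error: M, K, Q must be finite", call. = FALSE)
  }
  if (any(M < 0) || any(K < 0) || any(Q < 0)) {
    stop("validation error: M, K, Q must be non-negative", call. = FALSE)
  }
  cf_at <- function(S) M * (1 + S) / ((1 + S) + Q * K)
  g <- function(S) sum(K * cf_at(S)) - S
  S_max <- sum(K * M)
  if (S_max == 0) {
    S <- 0
  } else {
    root <- stats::uniroot(g, lower = 0, upper = S_max,
                           f.lower = g(0), f.upper = g(S_max),
                           tol = max(.Machine$double.eps, tol * S_max),
                           maxiter = 1000L)
    S <- root$root
    # Newton polish: g'(S) = sum(M K^2 Q / ((1+S)+QK)^2) - 1 < 0.
    for (it in 1:4) {
      gp <- sum(M * K^2 * Q / (((1 + S) + Q * K)^2)) - 1
      step <- g(S) / gp
      S_new <- S - step
      if (!is.finite(S_new) || S_new < 0) break
      S <- S_new
      if (abs(step) <= tol * max(S, 1)) break
    }
  }
  C_F <- cf_at(S)
  C_S <- M - C_F
  S_chk <- sum(K * C_F)
  resid <- max(abs(C_F + C_S - M),
               abs(C_S - Q * K * C_F / (1 + S_chk)))
  if (resid > 1e-6 * max(M, 1)) {
    stop("numerical error: partition solver residual ", format(resid),
         " with S in [0, ", format(S_max), "]", call. = FALSE)
  }
  structure(list(C_F = C_F, C_S = C_S, S = S, residual = resid),
            class = "phx_partition")
}

#' Brute-force competitive Langmuir solver (verification path)
#'
#' Solves the same partition problem as [solve_partition()] by damped
#' fixed-point iteration on the full per-species system, starting from
#' everything free (\code{C_F = M}). Intended as an independent cross-check
#' for small systems; the production path is [solve_partition()].
#'
#' @inheritParams solve_partition
#' @param max_iter Iteration cap (default 100000).
#' @param damping Damping factor in (0, 1] (default 0.5).
#' @return Same structure as [solve_partition()].
#' @export
partition_oracle <- function(M, K, Q, tol = 1e-13, max_iter = 100000L,
                             damping = 0.5) {
  n <- length(M)
  stopifnot(length(K) == n, length(Q) == n)
  C_F <- M
  for (it in seq_len(max_iter)) {
    S <- sum(K * C_F)
    # With S frozen, conservation C_F + Q K C_F/(1+S) = M is linear in C_F.
    target <- M / (1 + Q * K / (1 + S))
    C_new <- (1 - damping) * C_F + damping * target
    delta <- max(abs(C_new - C_F))
    C_F <- C_new
    if (delta <= tol * max(M, 1)) break
  }
  if (delta > tol * max(M, 1)) {
    stop("numerical error: partition oracle did not converge (last step ",
         format(delta), ")", call. = FALSE)
  }
  S <- sum(K * C_F)
  C_S <- M - C_F
  structure(list(C_F = C_F, C_S = C_S, S = S,
                 residual = max(abs(C_S - Q * K * C_F / (1 + S)))),
            class = "phx_partition")
}

#' Competitive Langmuir surface loading
#'
#' Per-species loading of the cell-wall adsorbent,
#' \code{q_i = q_m,i K_i C_F,i / (1 + sum_j K_j C_F,j)} in mg of species per
#' g of adsorbent. Strictly below \code{q_m} for finite concentrations.
#'
#' @param C_F Free-concentration vector, mg/L.
#' @param K Langmuir constants, L/mg.
#' @param q_m Adsorption capacities, mg/g.
#' @return Loadings \code{q}, mg/g, same length as \code{C_F}.
#' @export
langmuir_loading <- function(C_F, K, q_m) {
  if (any(C_F < 0)) {
    stop("validation error: free concentrations must be non-negative",
         call. = FALSE)
  }
  q_m * K * C_F / (1 + sum(K * C_F))
}

#' @export
print.phx_partition <- function(x, ...) {
  cat("Competitive Langmuir partition\n")
  df <- data.frame(C_F = x$C_F, C_S = x$C_S)
  print(df, ...)
  cat("saturation sum S =", format(x$S),
      "; residual =", format(x$residual), "mg/L\n")
  invisible(x)
}
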