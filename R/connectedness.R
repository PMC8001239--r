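#' Generalized forecast-error variance decomposition
#'
#' For an N-variable VAR with MA coefficients \eqn{\Psi_h} and innovation
#' covariance \eqn{\Sigma}, the H-step generalized share of series i's
#' forecast-error variance attributed to shocks in series j is
#' \deqn{\theta_{ij} = \frac{\sigma_{jj}^{-1} \sum_{h=0}^{H-1}
#'   (e_i' \Psi_h \Sigma e_j)^2}{\sum_{h=0}^{H-1} e_i' \Psi_h \Sigma \Psi_h'
#'   e_i}.}
#' Because generalized shocks are not orthogonal the raw rows do not sum to
#' one; each row is normalized to sum to exactly 1.  The decomposition is
#' invariant to the ordering of the series.
#'
#' @param params A [var_params()] object, or a list with elements `A`
#'   (coefficient stack) and `Sigma`.
#' @param H Forecast horizon (>= 1).
#' @return Object of class `fevd_matrix`: list with `phi` (row-normalized
#'   N x N share matrix), `theta` (raw shares), `H`.
#' @export
gfevd <- function(params, H = 10L) {
  if (!inherits(params, "var_params")) {
    if (!is.list(params) || is.null(params$A) || is.null(params$Sigma))
      stop_input("params must be var_params or list(A=, Sigma=)")
  }
  H <- as.integer(H)
  if (H < 1) stop_input("horizon H must be >= 1")
  Sigma <- symmetrize(as.matrix(params$Sigma))
  if (any(diag(Sigma) <= 0))
    stop_input("Sigma has a non-positive diagonal entry (series %d)",
               which(diag(Sigma) <= 0)[1])
  Psi <- ma_coefficients(params$A, H)   # Psi_0 .. Psi_H; use first H
  N <- nrow(Sigma)
  num <- matrix(0, N, N)
  den <- rep(0, N)
  for (h in seq_len(H)) {
    PS <- Psi[[h]] %*% Sigma            # Psi_{h-1} Sigma
    num <- num + PS^2
    den <- den + rowSums(PS * Psi[[h]]) # diag(Psi Sigma Psi')
  }
  theta <- sweep(num, 2, diag(Sigma), "/")
  theta <- theta / den
  phi <- theta / rowSums(theta)
  dimnames(phi) <- dimnames(theta) <- dimnames(Sigma)
  structure(list(phi = phi, theta = theta, H = H), class = "fevd_matrix")
}

#' @export
print.fevd_matrix <- function(x, ...) {
  cat(sprintf("<fevd_matrix> N = %d, H = %d\n", nrow(x$phi), x$H))
  invisible(x)
}

#' Connectedness index family from a normalized FEVD matrix
#'
#' Computes, in percent:
#' \itemize{
#'   \item `from[i] = 100 * sum_{j != i} phi[i, j]` — spillovers received;
#'   \item `to[i] = 100 * sum_{j != i} phi[j, i]` — spillovers transmitted;
#'   \item `ntdci[i] = to[i] - from[i]` — net total directional index;
#'   \item `npdci[i, j] = 100 * (phi[j, i] - phi[i, j])` — net pairwise
#'     index (positive: i is a net transmitter to j);
#'   \item `tci = mean(from) = mean(to)` — total connectedness.
#' }
#' The indices satisfy `sum(ntdci) = 0`, `npdci = -t(npdci)` and
#' `ntdci = rowSums(npdci)` by construction.  `tci` uses the N denominator;
#' set `denominator = "N-1"` for the alternative convention.
#'
#' @param fevd An [gfevd()] result (or row-stochastic matrix).
#' @param time Label for the period (default `"static"`).
#' @param denominator `"N"` (default) or `"N-1"` for the TCI scaling.
#' @return Object of class `connectedness_table`.
#' @export
connectedness_indices <- function(fevd, time = "static",
                                  denominator = c("N", "N-1")) {
  denominator <- match.arg(denominator)
  phi <- if (inherits(fevd, "fevd_matrix")) fevd$phi else as.matrix(fevd)
  N <- nrow(phi)
  if (ncol(phi) != N) stop_input("FEVD matrix must be square")
  if (any(phi < -1e-12)) stop_input("FEVD matrix has negative entries")
  if (max(abs(rowSums(phi) - 1)) > 1e-8)
    stop_input("FEVD rows must sum to 1")
  off_from <- 100 * (rowSums(phi) - diag(phi))
  off_to <- 100 * (colSums(phi) - diag(phi))
  npdci <- 100 * (t(phi) - phi)
  denom <- if (denominator == "N") N else N - 1
  ids <- rownames(phi) %||% paste0("CCS", seq_len(N))
  names(off_from) <- names(off_to) <- ids
  dimnames(npdci) <- list(ids, ids)
  structure(
    list(time = time, n_series = N, H = if (inherits(fevd, "fevd_matrix")) fevd$H else NA,
         tci = sum(off_from) / denom,
         to = off_to, from = off_from,
         ntdci = off_to - off_from, npdci = npdci,
         fevd = phi, denominator = denominator),
    class = "connectedness_table"
  )
}

#' @export
print.connectedness_table <- function(x, ...) {
  cat(sprintf("<connectedness_table> [%s] N = %d, TCI = %.2f%%\n",
              as.character(x$time), x$n_series, x$tci))
  top <- sort(x$ntdci, decreasing = TRUE)
  cat("  top net transmitter:", names(top)[1], sprintf("(%.2f)", top[1]), "\n")
  cat("  top net receiver:   ", names(top)[length(top)],
      sprintf("(%.2f)", top[length(top)]), "\n")
  invisible(x)
}

#' Dynamic connectedness from TVP-VAR states
#'
#' Applies [gfevd()] and [connectedness_indices()] to each period's
#' coefficient stack and innovation covariance.
#'
#' @param states A [fit_tvp_var()] result.
#' @param H Forecast horizon (default 10).
#' @param denominator TCI scaling convention, see [connectedness_indices()].
#' @return Object of class `dynamic_connectedness`: list with `tables` (one
#'   `connectedness_table` per period), `tci` (vector), `ntdci`, `to`, `from`
#'   (period x series matrices), `dates`, `H`.
#' @export
dynamic_connectedness <- function(states, H = 10L,
                                  denominator = c("N", "N-1")) {
  denominator <- match.arg(denominator)
  if (!inherits(states, "tvpvar_states"))
    stop_input("states must come from fit_tvp_var()")
  Teff <- states$n_periods
  if (Teff < 1) stop_input("empty state sequence")
  tables <- vector("list", Teff)
  for (t in seq_len(Teff)) {
    pr <- state_params(states, t)
    tab <- tryCatch(
      connectedness_indices(gfevd(pr, H), time = states$dates[t],
                            denominator = denominator),
      error = function(e)
        stop_input("connectedness failed at period %s: %s",
                   format(states$dates[t]), conditionMessage(e)))
    if (is.null(rownames(tab$fevd))) {
      names(tab$to) <- names(tab$from) <- names(tab$ntdci) <- states$series_ids
    }
    tables[[t]] <- tab
  }
  ids <- states$series_ids
  structure(
    list(tables = tables,
         tci = vapply(tables, `[[`, 0, "tci"),
         ntdci = matrix(t(vapply(tables, `[[`, numeric(states$n_series),
                                 "ntdci")),
                        Teff, states$n_series, dimnames = list(NULL, ids)),
         to = matrix(t(vapply(tables, `[[`, numeric(states$n_series), "to")),
                     Teff, states$n_series, dimnames = list(NULL, ids)),
         from = matrix(t(vapply(tables, `[[`, numeric(states$n_series),
                                "from")),
                       Teff, states$n_series, dimnames = list(NULL, ids)),
         dates = states$dates, H = H, series_ids = ids),
    class = "dynamic_connectedness"
  )
}

#' @export
print.dynamic_connectedness <- function(x, ...) {
  cat(sprintf(
    "<dynamic_connectedness> %d periods x %d series, mean TCI = %.2f%%\n",
    length(x$tci), length(x$series_ids), mean(x$tci)))
  invisible(x)
}

#' Static (time-averaged) connectedness table
#'
#' Element-wise mean of the per-period normalized FEVD matrices with all
#' indices recomputed from the averaged matrix — the time-varying analogue of
#' a full-sample spillover table.
#'
#' @param dynamic A [dynamic_connectedness()] result.
#' @param denominator TCI convention.
#' @return A `connectedness_table` labelled `"static"`.
#' @export
average_table <- function(dynamic, denominator = c("N", "N-1")) {
  denominator <- match.arg(denominator)
  if (!inherits(dynamic, "dynamic_connectedness"))
    stop_input("input must be dynamic_connectedness")
  if (!length(dynamic$tables)) stop_input("empty table sequence")
  phis <- lapply(dynamic$tables, `[[`, "fevd")
  avg <- Reduce(`+`, phis) / length(phis)
  connectedness_indices(avg, time = "static", denominator = denominator)
}

#' Classify series as spillover transmitters / receivers
#'
#' Role is the sign of the time-mean net index; purity requires a strict
#' uniform sign over every period (an exact zero breaks purity).
#'
#' @param dynamic A [dynamic_connectedness()] result.
#' @return Data frame with `series`, `mean_ntdci`, `role`
#'   (`net transmitter` / `net receiver`), `purity` (`pure transmitter`,
#'   `pure receiver`, `in-between`).
#' @export
classify_nodes <- function(dynamic) {
  if (!inherits(dynamic, "dynamic_connectedness"))
    stop_input("input must be dynamic_connectedness")
  M <- dynamic$ntdci
  mean_ntdci <- colMeans(M)
  role <- ifelse(mean_ntdci > 0, "net transmitter", "net receiver")
  purity <- apply(M, 2, function(v) {
    if (all(v > 0)) "pure transmitter"
    else if (all(v < 0)) "pure receiver"
    else "in-between"
  })
  data.frame(series = colnames(M), mean_ntdci = mean_ntdci, role = role,
             purity = purity, row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a connectedness table as a directed spillover network
#'
#' One directed edge per unordered pair with a nonzero net pairwise index,
#' oriented from the net transmitter to the net receiver, weighted by the
#' absolute net pairwise index, and filtered at a minimum weight.
#'
#' @param table A `connectedness_table`.
#' @param min_edge Minimum edge weight retained (>= 0, default 0; zero-weight
#'   pairs are always dropped).
#' @return Object of class `spill_network`: list with `edges`
#'   (`from`, `to`, `weight`) and `nodes` (`id`, `ntdci`, `role`).
#' @export
export_network <- function(table, min_edge = 0) {
  if (!inherits(table, "connectedness_table"))
    stop_input("table must be a connectedness_table")
  if (min_edge < 0) stop_input("min_edge must be >= 0")
  np <- table$npdci
  ids <- rownames(np)
  N <- nrow(np)
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      v <- np[i, j]
      if (v == 0 || abs(v) < min_edge) next
      if (v > 0) { from <- c(from, ids[i]); to <- c(to, ids[j]) }
      else { from <- c(from, ids[j]); to <- c(to, ids[i]) }
      w <- c(w, abs(v))
    }
  }
  nodes <- data.frame(id = ids, ntdci = as.numeric(table$ntdci),
                      role = ifelse(table$ntdci > 0, "net transmitter",
                                    "net receiver"),
                      stringsAsFactors = FALSE)
  structure(list(edges = data.frame(from = from, to = to, weight = w,
                                    stringsAsFactors = FALSE),
                 nodes = nodes, min_edge = min_edge),
            class = "spill_network")
}

#' @export
print.spill_network <- function(x, ...) {
  cat(sprintf("<spill_network> %d nodes, %d edges (min_edge = %g)\n",
              nrow(x$nodes), nrow(x$edges), x$min_edge))
  invisible(x)
}

#' Write a spillover network as CSV edge list and DOT graph
#'
#' @param network An [export_network()] result.
#' @param edge_csv,dot_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, edge_csv = NULL, dot_path = NULL) {
  stopifnot(inherits(network, "spill_network"))
  if (!is.null(edge_csv))
    utils::write.csv(network$edges, edge_csv, row.names = FALSE)
  if (!is.null(dot_path)) {
    lines <- c("digraph spillovers {")
    for (r in seq_len(nrow(network$nodes))) {
      nd <- network$nodes[r, ]
      lines <- c(lines, sprintf(
        "  \"%s\" [ntdci=%.4f, color=%s];", nd$id, nd$ntdci,
        if (nd$role == "net transmitter") "red" else "green"))
    }
    for (r in seq_len(nrow(network$edges))) {
      ed <- network$edges[r, ]
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [weight=%.6f];",
                                ed$from, ed$to, ed$weight))
    }
    lines <- c(lines, "}")
    writeLines(lines, dot_path)
  }
  invisible(c(edge_csv, dot_path))
}
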