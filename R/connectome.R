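# Connectome communication analysis: load or synthesise a signed, weighted,
# directed synapse network with node classes, stabilise its linearised
# dynamics, select sensory inputs / motor outputs, and compare rate curves
# against symmetrized and direction-randomized nulls.

#' Construct a connectome object
#'
#' @param A_signed Signed weighted adjacency, orientation `A[post, pre]`.
#' @param node_ids Character labels, one per node.
#' @param node_class Named character vector mapping each label to
#'   `"sensory"`, `"inter"` or `"motor"`.
#' @param inhibitory Character vector of labels of inhibitory (GABAergic)
#'   nodes; their outgoing weights (columns) must be `<= 0`, all others
#'   `>= 0`.
#' @return An object of class `connectome`.
#' @export
connectome <- function(A_signed, node_ids, node_class, inhibitory = character()) {
  assert_square(A_signed)
  n <- nrow(A_signed)
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("`node_ids` length must match the matrix", call. = FALSE)
  if (anyDuplicated(node_ids)) stop("duplicate node ids", call. = FALSE)
  node_class <- node_class[node_ids]
  if (any(is.na(node_class)) || !all(node_class %in% c("sensory", "inter", "motor")))
    stop("every node needs a class in {sensory, inter, motor}", call. = FALSE)
  if (!all(inhibitory %in% node_ids)) stop("inhibitory labels not among node ids", call. = FALSE)
  inh_col <- node_ids %in% inhibitory
  if (any(A_signed[, inh_col] > 0))
    stop("outgoing weights of inhibitory nodes must be <= 0", call. = FALSE)
  if (any(A_signed[, !inh_col] < 0))
    stop("outgoing weights of excitatory nodes must be >= 0", call. = FALSE)
  dimnames(A_signed) <- list(node_ids, node_ids)
  structure(list(A_signed = A_signed, node_ids = node_ids,
                 node_class = node_class, inhibitory = inhibitory),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cl <- table(factor(x$node_class, levels = c("sensory", "inter", "motor")))
  cat(sprintf("<connectome> %d nodes (%d sensory, %d inter, %d motor), %d inhibitory\n",
              length(x$node_ids), cl[["sensory"]], cl[["inter"]], cl[["motor"]],
              length(x$inhibitory)))
  cat(sprintf("  %d directed edges, weight range [%g, %g]\n",
              sum(x$A_signed != 0), min(x$A_signed), max(x$A_signed)))
  invisible(x)
}

#' Load a connectome from edge-list and class-table files
#'
#' The edge list is delimited text with columns (pre-synaptic id,
#' post-synaptic id, weight >= 0), an optional header; the class table has
#' columns (id, class in sensory/inter/motor, gabaergic flag 0/1).
#' Orientation follows the package convention `A[post, pre] = weight`;
#' duplicate directed edges are summed (with a message). All outgoing
#' weights of GABAergic nodes are made negative (inhibitory synapses); the
#' rest stay excitatory.
#'
#' @param edges_path,classes_path File paths (comma- or
#'   whitespace-delimited).
#' @return A [connectome()].
#' @export
load_connectome <- function(edges_path, classes_path) {
  edges <- read_delim_flex(edges_path, c("pre", "post", "weight"))
  classes <- read_delim_flex(classes_path, c("id", "class", "gabaergic"))
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop("edge weights must be finite and nonnegative", call. = FALSE)
  ids <- as.character(classes$id)
  unknown <- setdiff(unique(c(edges$pre, edges$post)), ids)
  if (length(unknown) > 0)
    stop("edge list references node ids missing from the class table: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  key <- paste(edges$pre, edges$post)
  if (anyDuplicated(key)) message("duplicate directed edges found; weights summed")
  for (r in seq_len(nrow(edges))) {
    A[edges$post[r], edges$pre[r]] <- A[edges$post[r], edges$pre[r]] + edges$weight[r]
  }
  inhib <- ids[as.integer(classes$gabaergic) == 1L]
  A[, ids %in% inhib] <- -A[, ids %in% inhib]
  cls <- stats::setNames(as.character(classes$class), ids)
  connectome(A, ids, cls, inhib)
}

# whitespace- or comma-delimited reader with optional header
read_delim_flex <- function(path, col_names) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  txt <- gsub("[,\t]", " ", lines)
  first <- strsplit(trimws(txt[1]), "\\s+")[[1]]
  has_header <- suppressWarnings(is.na(as.numeric(first[length(first)])))
  df <- utils::read.table(text = txt, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < length(col_names))
    stop("expected at least ", length(col_names), " columns in ", path, call. = FALSE)
  df <- df[, seq_along(col_names)]
  names(df) <- col_names
  df[] <- lapply(df, function(x) if (is.numeric(x)) x else as.character(x))
  df
}

#' Write a connectome to edge-list and class-table files
#'
#' Inverse of [load_connectome()]: weights are written unsigned (the sign
#' is a consequence of the GABAergic flag).
#'
#' @param cn A [connectome()].
#' @param edges_path,classes_path Output file paths (CSV).
#' @export
write_connectome <- function(cn, edges_path, classes_path) {
  idx <- which(cn$A_signed != 0, arr.ind = TRUE)
  edges <- data.frame(pre = cn$node_ids[idx[, 2]],
                      post = cn$node_ids[idx[, 1]],
                      weight = abs(cn$A_signed[idx]))
  edges <- edges[order(edges$pre, edges$post), ]
  utils::write.csv(edges, edges_path, row.names = FALSE, quote = FALSE)
  classes <- data.frame(id = cn$node_ids,
                        class = unname(cn$node_class),
                        gabaergic = as.integer(cn$node_ids %in% cn$inhibitory))
  utils::write.csv(classes, classes_path, row.names = FALSE, quote = FALSE)
  invisible(c(edges_path, classes_path))
}

#' Synthetic connectome fixture
#'
#' Generates a directed, weighted, signed graph emulating the schema of the
#' C. elegans chemical-synapse dataset: three node classes (default
#' proportions 88:82:107 sensory:inter:motor), an inhibitory subset
#' (default fraction 26/279) whose outgoing synapses are negative,
#' integer-valued positive weights, and a tunable feedforward bias along
#' sensory -> inter -> motor. `directionality = 0` gives no directed
#' structure in expectation; large values concentrate edges in the forward
#' direction. This is a synthetic stand-in for testing; it reproduces the
#' data schema, not the real wiring.
#'
#' @param n Number of nodes.
#' @param class_fractions Numeric length-3 vector (sensory, inter, motor)
#'   summing to 1.
#' @param inhib_fraction Fraction of inhibitory nodes.
#' @param directionality Nonnegative feedforward bias; forward edges are
#'   `(1 + directionality)` times as likely as the baseline, backward edges
#'   `1 / (1 + directionality)` times.
#' @param density Expected fraction of ordered node pairs connected
#'   (default matches the real network's 2194 edges over 279 nodes).
#' @param seed Integer seed.
#' @return A [connectome()].
#' @examples
#' cn <- synthetic_connectome(30, seed = 1)
#' @export
synthetic_connectome <- function(n = 30,
                                 class_fractions = c(sensory = 88, inter = 82, motor = 107) / 277,
                                 inhib_fraction = 26 / 279,
                                 directionality = 1.5,
                                 density = 2194 / (279 * 278),
                                 seed = 1L) {
  if (abs(sum(class_fractions) - 1) > 1e-8) stop("`class_fractions` must sum to 1", call. = FALSE)
  if (directionality < 0) stop("`directionality` must be nonnegative", call. = FALSE)
  withr::with_seed(seed, {
    counts <- diff(c(0, round(cumsum(class_fractions) * n)))
    counts[3] <- n - counts[1] - counts[2]
    cls <- rep(c("sensory", "inter", "motor"), counts)
    ids <- sprintf("%s%02d", c("S", "I", "M")[match(cls, c("sensory", "inter", "motor"))],
                   stats::ave(seq_len(n), cls, FUN = seq_along))
    rank <- match(cls, c("sensory", "inter", "motor"))
    # multiplicative feedforward bias, renormalised to the target density
    mult <- outer(rank, rank, function(rpost, rpre) {
      ifelse(rpost > rpre, 1 + directionality,
             ifelse(rpost < rpre, 1 / (1 + directionality), 1))
    })
    diag(mult) <- 0
    p <- density * mult / mean(mult[mult > 0])
    p <- pmin(p, 1)
    adj <- matrix(stats::runif(n * n) < p, n, n)
    diag(adj) <- FALSE
    W <- matrix(0, n, n)
    ne <- sum(adj)
    W[adj] <- 1 + stats::rpois(ne, lambda = 2)
    inhib <- sample(ids, size = max(0, round(inhib_fraction * n)))
    W[, ids %in% inhib] <- -W[, ids %in% inhib]
    connectome(W, ids, stats::setNames(cls, ids), inhib)
  })
}

#' Stabilized linear dynamics of a connectome
#'
#' Places the signed adjacency into the linear membrane-potential model
#' `tau dx/dt = (A - gamma I) x`, choosing the spectral shift `gamma` so
#' the slowest mode of `(A - gamma I)/tau` decays at exactly `target`.
#'
#' @param cn A [connectome()].
#' @param tau Membrane time constant (default 0.5).
#' @param target Largest eigenvalue real part after stabilization
#'   (default -0.1).
#' @return A list with `A_dyn` and `gamma` (see [stabilize_spectrum()]).
#' @export
stabilized_dynamics <- function(cn, tau = 0.5, target = -0.1) {
  stopifnot(inherits(cn, "connectome"))
  stabilize_spectrum(cn$A_signed, tau = tau, target = target)
}

#' Input/output selectors by node class
#'
#' Builds 0/1 selector matrices: `B` (`n x m`) with one unit column per
#' input node, `C` (`p x n`) with one unit row per output node. Class
#' `"all"` gives the identity (full communication setting).
#'
#' @param cn A [connectome()].
#' @param input_class,output_class One of `"sensory"`, `"inter"`,
#'   `"motor"`, `"all"`, or a character vector of node ids.
#' @return `list(B, C)`.
#' @export
class_selectors <- function(cn, input_class = "sensory", output_class = "motor") {
  stopifnot(inherits(cn, "connectome"))
  n <- length(cn$node_ids)
  pick <- function(spec) {
    if (identical(spec, "all")) return(seq_len(n))
    if (all(spec %in% c("sensory", "inter", "motor")))
      return(which(cn$node_class %in% spec))
    idx <- match(spec, cn$node_ids)
    if (any(is.na(idx))) stop("unknown node ids in selector spec", call. = FALSE)
    idx
  }
  bi <- pick(input_class); ci <- pick(output_class)
  I <- diag(n)
  list(B = I[, bi, drop = FALSE], C = I[ci, , drop = FALSE])
}

#' Random nonoverlapping selectors
#'
#' Draws disjoint random input and output node sets of given sizes — the
#' null against which the sensory-in / motor-out arrangement is compared.
#'
#' @param cn A [connectome()].
#' @param m,p Number of input and output nodes (`m + p <= n`).
#' @param seed Integer seed.
#' @return `list(B, C)`.
#' @export
random_selectors <- function(cn, m, p, seed = 1L) {
  stopifnot(inherits(cn, "connectome"))
  n <- length(cn$node_ids)
  if (m + p > n) stop("`m + p` must not exceed the number of nodes", call. = FALSE)
  withr::with_seed(seed, {
    perm <- sample.int(n)
    bi <- perm[seq_len(m)]
    ci <- perm[m + seq_len(p)]
    I <- diag(n)
    list(B = I[, bi, drop = FALSE], C = I[ci, , drop = FALSE])
  })
}

#' Information-rate curve over transmission windows
#'
#' Computes `R_T` for each window on the grid for the channel
#' `(A_dyn, B, C, sigma2)`. Per-point failures are recorded (`NA` rate,
#' `error` flag) and the rest of the curve is still returned.
#'
#' @param A_dyn Stable dynamics matrix.
#' @param B,C Selector matrices (`NULL` for identity).
#' @param windows Positive window grid.
#' @param sigma2 Readout noise variance (default 1).
#' @param opts Optimizer options.
#' @param label Optional curve label carried into the result.
#' @return A tibble of class `rate_curve` with columns `window`,
#'   `capacity_bits`, `rate`, `n_eff`, `converged`, `error`, `label`.
#' @export
rate_sweep <- function(A_dyn, B = NULL, C = NULL,
                       windows = exp(seq(log(0.01), log(10), length.out = 30)),
                       sigma2 = 1, opts = optimizer_options(), label = "network") {
  rows <- lapply(windows, function(Tw) {
    out <- tryCatch({
      ch <- net_channel(A_dyn, B, C, window = Tw, sigma2 = sigma2)
      res <- capacity(ch, opts)
      tibble::tibble(window = Tw, capacity_bits = res$capacity_bits,
                     rate = res$rate_bits_per_time,
                     n_eff = res$input_dimensionality,
                     converged = res$converged, error = FALSE)
    }, error = function(e) {
      tibble::tibble(window = Tw, capacity_bits = NA_real_, rate = NA_real_,
                     n_eff = NA_real_, converged = NA, error = TRUE)
    })
    out
  })
  curve <- dplyr::bind_rows(rows)
  curve$label <- label
  class(curve) <- c("rate_curve", class(curve))
  curve
}

#' Rate curves of a randomized connectome ensemble
#'
#' Applies a randomizing manipulation to the connectome `n_real` times
#' (each realization is re-stabilized to the same spectral margin),
#' computes the rate curve of each realization, and aggregates the mean
#' and a 95% confidence band.
#'
#' Manipulations: `"direction-swap"` exchanges each signed entry pair
#' `(A[i,j], A[j,i])` with probability `swap_prob` (an inhibitory edge
#' stays inhibitory after reversal); `"random-BC"` keeps the network fixed
#' and draws fresh random nonoverlapping input/output sets of the sensory
#' and motor class sizes.
#'
#' @param cn A [connectome()].
#' @param manipulation `"direction-swap"` or `"random-BC"`.
#' @param n_real Number of realizations (`>= 2`).
#' @param windows Window grid.
#' @param sigma2 Readout noise variance.
#' @param seed Integer seed; realization `i` uses `seed + i`.
#' @param swap_prob Swap probability for `"direction-swap"` (default 1/2).
#' @param tau,target Stabilization parameters.
#' @param opts Optimizer options.
#' @param ci `"normal"` (mean +/- 1.96 SE) or `"bootstrap"` (percentile,
#'   1000 resamples).
#' @return A tibble of class `ensemble_curve` with columns `window`,
#'   `mean_rate`, `ci_low`, `ci_high`, `n_realizations`; per-realization
#'   spectral shifts are attached as attribute `"gammas"`.
#' @export
randomized_ensemble <- function(cn, manipulation = c("direction-swap", "random-BC"),
                                n_real = 10, windows = exp(seq(log(0.01), log(10), length.out = 30)),
                                sigma2 = 1, seed = 1L, swap_prob = 0.5,
                                tau = 0.5, target = -0.1,
                                opts = optimizer_options(), ci = c("normal", "bootstrap")) {
  stopifnot(inherits(cn, "connectome"))
  manipulation <- match.arg(manipulation)
  ci <- match.arg(ci)
  if (n_real < 2) stop("`n_real` must be at least 2", call. = FALSE)

  base_stab <- stabilized_dynamics(cn, tau, target)
  sel_sizes <- c(m = sum(cn$node_class == "sensory"),
                 p = sum(cn$node_class == "motor"))
  gammas <- numeric(n_real)
  rates <- matrix(NA_real_, n_real, length(windows))
  for (i in seq_len(n_real)) {
    seed_i <- seed + i
    if (manipulation == "direction-swap") {
      A_i <- randomize_directions(cn$A_signed, p = swap_prob, seed = seed_i)
      stab <- stabilize_spectrum(A_i, tau = tau, target = target)
      gammas[i] <- stab$gamma
      curve <- rate_sweep(stab$A_dyn, NULL, NULL, windows, sigma2, opts,
                          label = sprintf("swap-%d", i))
    } else {
      sel <- random_selectors(cn, sel_sizes[["m"]], sel_sizes[["p"]], seed = seed_i)
      gammas[i] <- base_stab$gamma
      curve <- rate_sweep(base_stab$A_dyn, sel$B, sel$C, windows, sigma2, opts,
                          label = sprintf("randBC-%d", i))
    }
    rates[i, ] <- curve$rate
  }
  mean_rate <- colMeans(rates, na.rm = TRUE)
  if (ci == "normal") {
    se <- apply(rates, 2, stats::sd, na.rm = TRUE) / sqrt(n_real)
    lo <- mean_rate - 1.96 * se
    hi <- mean_rate + 1.96 * se
  } else {
    qs <- apply(rates, 2, function(col) {
      bm <- replicate(1000, mean(sample(col, replace = TRUE), na.rm = TRUE))
      stats::quantile(bm, c(0.025, 0.975), na.rm = TRUE)
    })
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  out <- tibble::tibble(window = windows, mean_rate = mean_rate,
                        ci_low = pmin(lo, mean_rate), ci_high = pmax(hi, mean_rate),
                        n_realizations = n_real)
  attr(out, "gammas") <- gammas
  attr(out, "manipulation") <- manipulation
  class(out) <- c("ensemble_curve", class(out))
  out
}
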