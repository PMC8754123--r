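#' Wagner-parsimony reconstruction of gene-cluster gain and loss
#'
#' Minimum-change ancestral reconstruction of a binary presence/absence
#' character on a rooted species tree, with independent gain and loss
#' penalties (asymmetric Wagner parsimony). The reconstruction uses
#' Sankoff-style dynamic programming: a bottom-up pass accumulates, for each
#' node and state, the minimal subtree cost (minimum over child states plus
#' the transition penalty), then a top-down traceback assigns states.
#' Multifurcating nodes are handled natively. Tie-breaking: where both
#' states are optimal, a node takes its parent's state (no change on the
#' incoming branch); an optimal tie at the root resolves to `root_prefer`
#' (default absence, the conservative choice for a patchily distributed
#' accessory cluster). The number of tied choices is reported.
#'
#' @param tree Rooted `ape::phylo` tree (branch lengths ignored).
#' @param profile Named 0/1 vector (or single-column data.frame) keyed by
#'   tip label.
#' @param gain_cost,loss_cost Positive penalties for a 0 -> 1 and 1 -> 0
#'   transition (defaults 1 and 1).
#' @param root_prefer State taken at the root on a cost tie (0 or 1).
#' @return list of class `gainloss`: `states` (0/1 per node, tips first in
#'   `tree` order), `edges` (data.frame: parent, child, child_label,
#'   terminal, event in \{gain, loss, none\}), `n_gains`, `n_losses`,
#'   `terminal_gains`, `terminal_losses`, `cost`, `n_ties`.
#' @export
wagner_parsimony <- function(tree, profile, gain_cost = 1.0, loss_cost = 1.0,
                             root_prefer = 0L) {
  if (gain_cost <= 0 || loss_cost <= 0) stop("costs must be positive")
  profile <- as_profile(profile)
  missing <- setdiff(tree$tip.label, names(profile))
  if (length(missing) > 0L) {
    stop("leaf missing from profile: ", missing[[1L]])
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  trans <- matrix(c(0, gain_cost, loss_cost, 0), nrow = 2, byrow = TRUE)

  cost <- matrix(0, nrow = nnode, ncol = 2)
  tipstate <- profile[tree$tip.label]
  cost[seq_len(ntip), 1] <- ifelse(tipstate == 0, 0, Inf)
  cost[seq_len(ntip), 2] <- ifelse(tipstate == 1, 0, Inf)

  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    parent <- po[i, 1]; child <- po[i, 2]
    for (s in 1:2) {
      cost[parent, s] <- cost[parent, s] +
        min(cost[child, 1] + trans[s, 1], cost[child, 2] + trans[s, 2])
    }
  }

  root <- ntip + 1L
  states <- integer(nnode)
  n_ties <- 0L
  if (abs(cost[root, 1] - cost[root, 2]) < 1e-12) {
    states[root] <- root_prefer
    n_ties <- n_ties + 1L
  } else {
    states[root] <- which.min(cost[root, ]) - 1L
  }
  for (i in rev(seq_len(nrow(po)))) {  # preorder: parents before children
    parent <- po[i, 1]; child <- po[i, 2]
    ps <- states[parent] + 1L
    cands <- c(cost[child, 1] + trans[ps, 1], cost[child, 2] + trans[ps, 2])
    if (abs(cands[1] - cands[2]) < 1e-12) {
      states[child] <- states[parent]  # prefer no change on the branch
      n_ties <- n_ties + 1L
    } else {
      states[child] <- which.min(cands) - 1L
    }
  }

  edges <- data.frame(
    parent = po[, 1], child = po[, 2],
    child_label = ifelse(po[, 2] <= ntip, tree$tip.label[po[, 2]],
                         paste0("node", po[, 2])),
    terminal = po[, 2] <= ntip,
    stringsAsFactors = FALSE)
  ps <- states[edges$parent]; cs <- states[edges$child]
  edges$event <- ifelse(ps == 0 & cs == 1, "gain",
                        ifelse(ps == 1 & cs == 0, "loss", "none"))
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL

  res <- list(states = states, edges = edges,
              n_gains = sum(edges$event == "gain"),
              n_losses = sum(edges$event == "loss"),
              terminal_gains = sum(edges$event == "gain" & edges$terminal),
              terminal_losses = sum(edges$event == "loss" & edges$terminal),
              cost = min(cost[root, ]), n_ties = n_ties)
  class(res) <- "gainloss"
  res
}

as_profile <- function(profile) {
  if (is.data.frame(profile)) {
    v <- profile[[ncol(profile)]]
    names(v) <- if (ncol(profile) > 1L) profile[[1L]] else rownames(profile)
    profile <- v
  }
  profile <- vapply(profile, as.integer, integer(1))
  if (!all(profile %in% c(0L, 1L))) stop("profile states must be 0/1")
  profile
}

#' Exhaustive-enumeration parsimony oracle
#'
#' Enumerates every assignment of 0/1 states to the internal nodes and
#' returns the minimal total transition cost together with all optimal
#' assignments. Exponential in the number of internal nodes; refuses trees
#' with more than 20. Intended as an independent check on
#' [wagner_parsimony()], not for analysis.
#'
#' @inheritParams wagner_parsimony
#' @return list: `cost`, `assignments` (matrix, one row per optimal internal
#'   assignment, columns = internal nodes in number order).
#' @export
brute_force_parsimony <- function(tree, profile, gain_cost = 1.0,
                                  loss_cost = 1.0) {
  if (tree$Nnode > 20L) stop("tree too large for exhaustive enumeration")
  profile <- as_profile(profile)
  ntip <- length(tree$tip.label)
  trans <- matrix(c(0, gain_cost, loss_cost, 0), nrow = 2, byrow = TRUE)
  edge <- tree$edge
  tipstate <- unname(profile[tree$tip.label])
  best <- Inf
  optimal <- list()
  for (code in 0:(2^tree$Nnode - 1L)) {
    internal <- as.integer(intToBits(code)[seq_len(tree$Nnode)])
    states <- c(tipstate, internal)
    cost <- sum(trans[cbind(states[edge[, 1]] + 1L, states[edge[, 2]] + 1L)])
    if (cost < best - 1e-12) {
      best <- cost
      optimal <- list(internal)
    } else if (abs(cost - best) < 1e-12) {
      optimal[[length(optimal) + 1L]] <- internal
    }
  }
  list(cost = best, assignments = do.call(rbind, optimal))
}

#' Totals and terminal-branch ("species-level") totals of gain/loss events
#'
#' @param result A `gainloss` result from [wagner_parsimony()].
#' @return One-row data.frame: `n_gains`, `n_losses`, `terminal_gains`,
#'   `terminal_losses`.
#' @export
event_summary <- function(result) {
  data.frame(n_gains = result$n_gains, n_losses = result$n_losses,
             terminal_gains = result$terminal_gains,
             terminal_losses = result$terminal_losses)
}

#' @export
print.gainloss <- function(x, ...) {
  cat("Wagner-parsimony gain/loss reconstruction\n")
  cat("  cost:", x$cost, " ties:", x$n_ties, "\n")
  cat("  gains:", x$n_gains, "(", x$terminal_gains, "on terminal branches )\n")
  cat("  losses:", x$n_losses, "(", x$terminal_losses,
      "on terminal branches )\n")
  invisible(x)
}

#' Simulate a gain/loss history of a binary character down a tree
#'
#' Two-state continuous-time Markov process (rates `gain_rate` for 0 -> 1,
#' `loss_rate` for 1 -> 0) evolved from the root along each branch
#' (edge lengths; 1 where absent). The full path is simulated, but per
#' branch only the effective change is recorded: a branch whose start and
#' end states differ contributes one gain or loss to the true-event count,
#' so parsimony reconstructions are comparable (and bounded above by the
#' truth).
#'
#' @param tree Rooted `ape::phylo` tree.
#' @param gain_rate,loss_rate Non-negative transition rates per unit branch
#'   length.
#' @param root_state Character state at the root (0 or 1).
#' @param seed Optional integer seed.
#' @return list: `tip_profile` (named 0/1 over tips), `states` (all nodes),
#'   `edges` (with `event` column), `n_gains`, `n_losses`, `n_events`.
#' @export
simulate_gainloss_history <- function(tree, gain_rate, loss_rate,
                                      root_state = 0L, seed = NULL) {
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  lens <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge)) else
    tree$edge.length
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))  # preorder
  lens <- if (is.null(po$edge.length)) rep(1, nrow(po$edge)) else
    po$edge.length
  states <- rep(NA_integer_, nnode)
  states[ntip + 1L] <- as.integer(root_state)
  rates <- c(gain_rate, loss_rate)  # out-rate from state 0, from state 1
  for (i in ord) {
    parent <- po$edge[i, 1]; child <- po$edge[i, 2]
    s <- states[parent]
    t_remaining <- lens[i]
    repeat {
      r <- rates[s + 1L]
      if (r <= 0) break
      wait <- stats::rexp(1, r)
      if (wait > t_remaining) break
      t_remaining <- t_remaining - wait
      s <- 1L - s
    }
    states[child] <- s
  }
  edges <- data.frame(parent = po$edge[, 1], child = po$edge[, 2],
                      terminal = po$edge[, 2] <= ntip)
  ps <- states[edges$parent]; cs <- states[edges$child]
  edges$event <- ifelse(ps == 0 & cs == 1, "gain",
                        ifelse(ps == 1 & cs == 0, "loss", "none"))
  tip_profile <- states[seq_len(ntip)]
  names(tip_profile) <- tree$tip.label
  list(tip_profile = tip_profile, states = states, edges = edges,
       n_gains = sum(edges$event == "gain"),
       n_losses = sum(edges$event == "loss"),
       n_events = sum(edges$event != "none"))
}

#' Read / write a single-character presence profile
#'
#' TSV with columns `label` and `state` (0/1), one row per tree leaf.
#'
#' @param path File path.
#' @return Named integer vector.
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  v <- as.integer(df$state)
  names(v) <- df$label
  as_profile(v)
}

#' @rdname read_profile
#' @param profile Named 0/1 vector.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(data.frame(label = names(profile),
                                state = as.integer(profile)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
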