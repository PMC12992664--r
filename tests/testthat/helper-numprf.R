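# shared fixtures, built once per test run

sched_vis <- build_run("visual")
sched_aud <- build_run("auditory")
hrf_default <- canonical_hrf()

# independent breadth-first-search connected components, used as the
# oracle for connected_clusters(); returns a list of sorted vertex sets
bfs_components <- function(edges, ids) {
  adj <- lapply(stats::setNames(vector("list", length(ids)),
                                as.character(ids)), identity)
  for (r in seq_len(nrow(edges))) {
    a <- as.character(edges[r, 1]); b <- as.character(edges[r, 2])
    adj[[a]] <- c(adj[[a]], edges[r, 2])
    adj[[b]] <- c(adj[[b]], edges[r, 1])
  }
  unseen <- ids
  comps <- list()
  while (length(unseen)) {
    queue <- unseen[1]
    comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!(v %in% unseen)) next
      unseen <- setdiff(unseen, v)
      comp <- c(comp, v)
      queue <- c(queue, intersect(adj[[as.character(v)]], unseen))
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# truth table helper for tuned-vertex simulations
make_truth <- function(n, mu, sigma_log, beta = 1, beta0 = 0,
                       noise_sd = 0.5) {
  tibble::tibble(vertex = seq_len(n), mu = mu, sigma_log = sigma_log,
                 beta = beta, beta0 = beta0, noise_sd = noise_sd)
}
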