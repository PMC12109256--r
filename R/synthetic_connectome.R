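# Default class mix: visual-system classes dominate (ME and ME>LO first),
# with sensory (input) and readout-associated (output) classes present so
# the whole-connectome input/intermediate/output partition is exercised.
DEFAULT_CLASS_TABLE <- c(
  "ME" = 0.32, "ME>LO" = 0.14, "LO" = 0.08, "bilateral" = 0.06,
  "CX" = 0.05, "Kenyon Cell" = 0.05, "LOP" = 0.04, "LA" = 0.03,
  "visual" = 0.04, "olfactory" = 0.03, "mechanosensory" = 0.02,
  "gustatory" = 0.01, "ocellar" = 0.01,
  "AN" = 0.02, "ALPN" = 0.02, "ME>LOP" = 0.02, "LO>LOP" = 0.01,
  "MBON" = 0.02, "DAN" = 0.02, "LHCENT" = 0.01, "TuBu" = 0.01,
  "clock" = 0.01, "pars intercerebralis" = 0.01,
  "ME.LO" = 0.01, "optic lobes" = 0.01)

#' Configuration for the synthetic connectome generator
#'
#' Defaults emulate the statistical structure the pipeline assumes of a
#' real fly-brain export: a class mix dominated by medulla classes, a
#' small-world wiring (rewired ring lattice) enriched with
#' preferential-attachment hub edges, connection scores drawn from a
#' two-component log-normal mixture (one mode per synaptic sign, giving the
#' bimodal heavy-tailed signed weight distribution), and a tunable share of
#' modulatory and sub-threshold synapses so every filter branch is hit.
#'
#' @param n_neurons number of neurons.
#' @param class_table named proportions over class labels (normalized).
#' @param lattice_degree even ring-lattice degree (local edges per node).
#' @param rewire_prob probability of rewiring each lattice edge's target.
#' @param hub_fraction fraction of neurons eligible as hubs.
#' @param hub_attachment extra hub-directed edges, as a multiple of
#'   `n_neurons`, attached preferentially by current degree.
#' @param excitatory_fraction fraction of synapses with excitatory sign.
#' @param meanlog_exc,sdlog_exc,meanlog_inh,sdlog_inh log-normal
#'   connection-score parameters per sign.
#' @param modulatory_fraction fraction of synapses whose argmax transmitter
#'   is modulatory (dropped downstream).
#' @param subthreshold_fraction fraction of synapses pushed below each
#'   quality threshold.
#' @param duplicate_fraction fraction of neuron pairs given a second
#'   parallel synapse (exercises aggregation).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_neurons = 2000,
                         class_table = DEFAULT_CLASS_TABLE,
                         lattice_degree = 8, rewire_prob = 0.1,
                         hub_fraction = 0.02, hub_attachment = 2,
                         excitatory_fraction = 0.6,
                         meanlog_exc = 5.3, sdlog_exc = 0.8,
                         meanlog_inh = 5.0, sdlog_inh = 0.7,
                         modulatory_fraction = 0.05,
                         subthreshold_fraction = 0.05,
                         duplicate_fraction = 0.1,
                         seed = 1L) {
  stopifnot(n_neurons >= 4, lattice_degree %% 2 == 0,
            lattice_degree >= 2,
            rewire_prob >= 0, rewire_prob <= 1,
            excitatory_fraction >= 0, excitatory_fraction <= 1,
            modulatory_fraction >= 0, modulatory_fraction <= 1,
            subthreshold_fraction >= 0, subthreshold_fraction <= 1)
  if (lattice_degree >= n_neurons)
    stop("lattice_degree must be smaller than n_neurons")
  ct <- class_table / sum(class_table)
  if (abs(sum(ct) - 1) > 1e-9) stop("class proportions must normalize to 1")
  structure(list(n_neurons = as.integer(n_neurons), class_table = ct,
                 lattice_degree = as.integer(lattice_degree),
                 rewire_prob = rewire_prob, hub_fraction = hub_fraction,
                 hub_attachment = hub_attachment,
                 excitatory_fraction = excitatory_fraction,
                 meanlog_exc = meanlog_exc, sdlog_exc = sdlog_exc,
                 meanlog_inh = meanlog_inh, sdlog_inh = sdlog_inh,
                 modulatory_fraction = modulatory_fraction,
                 subthreshold_fraction = subthreshold_fraction,
                 duplicate_fraction = duplicate_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate synthetic neuron and synapse tables
#'
#' @param config a [synth_config()].
#' @return list with `neurons` and `synapses` data frames in the
#'   FlyWire-style export schema accepted by [read_tables()].
#' @export
generate_connectome <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_neurons
  ids <- as.character(seq_len(n) + 1000L)
  # two mirrored spatial clusters (hemispheres)
  hemi <- rep(c(-1, 1), length.out = n)
  pos <- cbind(hemi * 2e5 + rnorm(n, 0, 5e4),
               rnorm(n, 4e5, 6e4), rnorm(n, 1e5, 4e4))
  quota <- largest_remainder_quota(n, config$class_table)
  classes <- sample(rep(names(quota), quota))
  neurons <- data.frame(neuron_id = ids, pos_x = pos[, 1], pos_y = pos[, 2],
                        pos_z = pos[, 3], cell_class = classes,
                        stringsAsFactors = FALSE)

  # --- wiring: directed rewired ring lattice + hub attachment ---
  k2 <- config$lattice_degree / 2
  pre <- rep(seq_len(n), each = k2)
  post <- as.integer((pre + rep(seq_len(k2), n) - 1L) %% n + 1L)
  rev_keep <- runif(n * k2) < 0.5  # half the lattice edges reversed
  tmp <- pre[rev_keep]
  pre[rev_keep] <- post[rev_keep]; post[rev_keep] <- tmp
  rw <- runif(length(pre)) < config$rewire_prob
  post[rw] <- sample.int(n, sum(rw), replace = TRUE)
  # hubs attract extra in-edges with probability proportional to degree
  n_extra <- round(config$hub_attachment * n)
  hubs <- sample.int(n, max(2, round(config$hub_fraction * n)))
  hub_w <- seq(length(hubs), 1)  # rank-based preferential attachment
  extra_post <- sample(hubs, n_extra, replace = TRUE, prob = hub_w)
  extra_pre <- sample.int(n, n_extra, replace = TRUE)
  pre <- c(pre, extra_pre); post <- c(post, extra_post)
  keep <- pre != post
  pre <- pre[keep]; post <- post[keep]
  dup <- !duplicated(cbind(pre, post))
  pre <- pre[dup]; post <- post[dup]
  m <- length(pre)
  # parallel synapses on a fraction of pairs
  extra <- which(runif(m) < config$duplicate_fraction)
  pre <- c(pre, pre[extra]); post <- c(post, post[extra])
  m <- length(pre)

  # --- per-synapse scores, signs, transmitter probabilities ---
  exc <- runif(m) < config$excitatory_fraction
  # shifted log-normals: smooth heavy tails entirely above the quality
  # threshold, one component per sign (bimodal signed weights)
  conn <- 100 + ifelse(exc,
                       stats::rlnorm(m, config$meanlog_exc, config$sdlog_exc),
                       stats::rlnorm(m, config$meanlog_inh, config$sdlog_inh))
  cleft <- 50 + stats::rgamma(m, shape = 6, scale = 20)
  sub_c <- runif(m) < config$subthreshold_fraction
  cleft[sub_c] <- runif(sum(sub_c), 0, 49.9)
  sub_k <- runif(m) < config$subthreshold_fraction
  conn[sub_k] <- runif(sum(sub_k), 0, 99.9)
  modu <- runif(m) < config$modulatory_fraction
  P <- matrix(runif(m * 6, 0, 0.05), m, 6)
  dom_exc <- sample(c(2L, 3L), m, replace = TRUE, prob = c(0.8, 0.2))
  dom <- ifelse(modu, sample(4:6, m, replace = TRUE),
                ifelse(exc, dom_exc, 1L))
  P[cbind(seq_len(m), dom)] <- runif(m, 0.6, 0.9)
  P <- P / rowSums(P)
  synapses <- data.frame(pre_id = ids[pre], post_id = ids[post],
                         cleft_score = round(cleft, 2),
                         connection_score = round(conn, 2),
                         stringsAsFactors = FALSE)
  synapses[paste0("p_", NT_ORDER)] <- round(P, 6)
  # renormalize after rounding so invariants hold exactly at read time
  list(neurons = neurons, synapses = synapses, config = config)
}

#' Generate, filter and build a synthetic connectome graph in one step
#'
#' Convenience wrapper: [generate_connectome()] then [filter_synapses()]
#' and [build_graph()], restricted to the largest weakly connected
#' component so selection preconditions hold.
#'
#' @param config a [synth_config()].
#' @return a `connectome_graph`.
#' @export
synthetic_graph <- function(config = synth_config()) {
  tabs <- generate_connectome(config)
  filt <- filter_synapses(tabs$synapses, tabs$neurons)
  g <- build_graph(tabs$neurons, filt)
  ig <- as_igraph(g)
  comp <- igraph::components(ig, mode = "weak")
  keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  induced_connectome(g, keep)
}

#' Hand-built 12-neuron fixture with its expected graph
#'
#' A deterministic 12-neuron, 30-synapse table covering every ingest
#' branch: sub-threshold cleft and connection scores, an orphan
#' post-synaptic id, modulatory-argmax drops, an exact mixed-sign
#' cancelling pair, parallel-synapse aggregation, and a GABA/ACh
#' probability tie. `expected_edges` is the hand-enumerated aggregated
#' signed edge list after filtering.
#'
#' @return list with `neurons`, `synapses` and `expected_edges`.
#' @export
make_fixture <- function() {
  ids <- as.character(101:112)
  classes <- c("ME", "ME", "ME", "ME>LO", "ME>LO", "LO", "LO", "CX",
               "MBON", "olfactory", "visual", "DAN")
  neurons <- data.frame(
    neuron_id = ids,
    pos_x = seq(1000, 12000, by = 1000),
    pos_y = rep(c(2000, 4000), 6),
    pos_z = rep(c(500, 700, 900), 4),
    cell_class = classes, stringsAsFactors = FALSE)
  p <- function(gaba = 0.02, ach = 0.02, glut = 0.02, oct = 0.02,
                ser = 0.02, da = 0.02) {
    v <- c(gaba, ach, glut, oct, ser, da)
    v / sum(v)
  }
  syn <- list(
    # clean excitatory chain 101 -> 102 -> 103
    list("101", "102", 120, 150, p(ach = 0.8)),
    list("102", "103", 130, 200, p(glut = 0.8)),
    # parallel excitatory pair 101 -> 103: aggregates to +120+130 = +250
    list("101", "103", 80, 120, p(ach = 0.8)),
    list("101", "103", 90, 130, p(ach = 0.7)),
    # inhibitory edges
    list("103", "104", 110, 300, p(gaba = 0.9)),
    list("104", "105", 70, 180, p(gaba = 0.7)),
    # mixed-sign cancelling pair 105 -> 106: +150 - 150 = 0, edge absent
    list("105", "106", 60, 150, p(ach = 0.8)),
    list("105", "106", 65, 150, p(gaba = 0.8)),
    # GABA/ACh exact tie 106 -> 107: priority order makes it inhibitory
    list("106", "107", 75, 140, p(gaba = 0.4, ach = 0.4)),
    # modulatory argmax synapses: dropped at sign assignment
    list("107", "108", 120, 250, p(oct = 0.8)),
    list("108", "109", 130, 260, p(ser = 0.8)),
    list("109", "110", 140, 270, p(da = 0.8)),
    # sub-threshold cleft (49 < 50): removed by the quality filter
    list("102", "104", 49, 500, p(ach = 0.8)),
    # sub-threshold connection (99 < 100): removed
    list("103", "105", 200, 99, p(ach = 0.8)),
    # orphan post-synaptic neuron: removed
    list("104", "999", 200, 500, p(ach = 0.8)),
    # boundary scores: exactly at both thresholds, retained
    list("107", "101", 50, 100, p(glut = 0.8)),
    # remaining clean synapses connecting the rest of the nodes
    list("108", "101", 90, 170, p(ach = 0.8)),
    list("109", "102", 95, 160, p(gaba = 0.8)),
    list("110", "103", 85, 210, p(ach = 0.8)),
    list("110", "111", 88, 190, p(glut = 0.8)),
    list("111", "112", 92, 220, p(ach = 0.8)),
    list("112", "101", 94, 230, p(gaba = 0.8)),
    list("105", "108", 96, 240, p(ach = 0.8)),
    list("106", "109", 97, 130, p(ach = 0.8)),
    list("104", "110", 98, 140, p(glut = 0.8)),
    list("101", "111", 99, 150, p(gaba = 0.8)),
    list("102", "112", 100, 160, p(ach = 0.8)),
    # a second parallel inhibitory synapse 103 -> 104: -300 - 110 = -410
    list("103", "104", 105, 110, p(gaba = 0.8)),
    # two more modulatory/sub-threshold rows to round out 30
    list("111", "101", 55, 95, p(ach = 0.8)),      # conn 95 < 100, removed
    list("112", "102", 45, 300, p(gaba = 0.8)))    # cleft 45 < 50, removed
  synapses <- data.frame(
    pre_id = vapply(syn, `[[`, "", 1),
    post_id = vapply(syn, `[[`, "", 2),
    cleft_score = vapply(syn, `[[`, 0, 3),
    connection_score = vapply(syn, `[[`, 0, 4),
    stringsAsFactors = FALSE)
  synapses[paste0("p_", NT_ORDER)] <-
    do.call(rbind, lapply(syn, `[[`, 5))
  expected_edges <- data.frame(
    pre  = c("101", "102", "101", "103", "104", "106", "107", "108",
             "109", "110", "110", "111", "112", "105", "106", "104",
             "101", "102"),
    post = c("102", "103", "103", "104", "105", "107", "101", "101",
             "102", "103", "111", "112", "101", "108", "109", "110",
             "111", "112"),
    weight = c(150, 200, 250, -410, -180, -140, 100, 170,
               -160, 210, 190, 220, -230, 240, 130, 140,
               -150, 160), stringsAsFactors = FALSE)
  list(neurons = neurons, synapses = synapses,
       expected_edges = expected_edges)
}

#' Write generated tables to CSV files
#'
#' @param tables list with `neurons` and `synapses` (from
#'   [generate_connectome()] or [make_fixture()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  np <- file.path(dir, "neurons.csv")
  sp <- file.path(dir, "synapses.csv")
  write.csv(tables$neurons, np, row.names = FALSE)
  write.csv(tables$synapses, sp, row.names = FALSE)
  invisible(c(neurons = np, synapses = sp))
}
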