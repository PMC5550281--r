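#' Default per-pair Poisson wiring rates
#'
#' Mean synapse counts per ordered (presynaptic cell, postsynaptic cell)
#' pair, by compartment, for the connection classes of the alpha lobe:
#' KC>MBON (per KC subtype), DAN>KC, KC>DAN and DAN>MBON. The defaults are
#' derived from the published census of the lobe (per-subtype connected
#' fractions and mean synapse numbers), expressed as unconditional per-pair
#' means, and give a full-scale connectome of roughly 8e4 contacts.
#'
#' @return Data frame with columns `pre_type`, `post_type`, `compartment`,
#'   `lambda`.
#' @export
default_wiring_rates <- function() {
  kc <- kc_subtypes() # s, c-o, c-i, p
  kcmbon <- rbind(
    data.frame(post_type = "MBON-a3",   compartment = "a3",
               pre_type = kc, lambda = c(16.10, 12.84, 11.31, 7.67)),
    data.frame(post_type = "MBON-a2sc", compartment = "a2",
               pre_type = kc, lambda = c(14.13, 13.67, 10.14, 0.86)),
    data.frame(post_type = "MBON-a2sp", compartment = "a2",
               pre_type = kc, lambda = c(4.24, 3.53, 1.29, 8.90)),
    data.frame(post_type = "MBON-a2p3p", compartment = "a2",
               pre_type = kc, lambda = c(0.42, 0.11, 0.014, 10.03)),
    data.frame(post_type = "MBON-a1",   compartment = "a1",
               pre_type = kc, lambda = c(10.80, 8.28, 7.47, 13.93)))
  dan <- data.frame(
    pre_type = c("PPL1-a3", "PPL1-ap2a2", "PAM-a1"),
    compartment = c("a3", "a2", "a1"))
  dankc <- data.frame(pre_type = dan$pre_type, post_type = "KC",
                      compartment = dan$compartment,
                      lambda = c(1.57, 0.77, 0.132))
  kcdan <- data.frame(pre_type = "KC", post_type = dan$pre_type,
                      compartment = dan$compartment,
                      lambda = c(2.65, 0.84, 0.201))
  danmbon <- data.frame(
    pre_type = c("PPL1-a3", "PPL1-ap2a2", "PPL1-ap2a2", "PPL1-ap2a2", "PAM-a1"),
    post_type = c("MBON-a3", "MBON-a2sc", "MBON-a2sp", "MBON-a2p3p", "MBON-a1"),
    compartment = c("a3", "a2", "a2", "a2", "a1"),
    lambda = c(227, 123, 45.5, 9.5, 45.7))
  out <- rbind(kcmbon[, c("pre_type", "post_type", "compartment", "lambda")],
               dankc, kcdan, danmbon)
  rownames(out) <- NULL
  out
}

default_extrinsic_census <- function() {
  data.frame(
    cell_type = c("MBON-a3", "PPL1-a3",
                  "MBON-a2sc", "MBON-a2sp", "MBON-a2p3p", "PPL1-ap2a2",
                  "MBON-a1", "PAM-a1"),
    compartment = c("a3", "a3", "a2", "a2", "a2", "a2", "a1", "a1"),
    n = c(2L, 2L, 1L, 1L, 2L, 2L, 2L, 16L),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic alpha-lobe generator
#'
#' The generator emulates the structure of a dense alpha-lobe synapse
#' table: ~1e3 Kenyon cells whose parallel axons traverse three serial
#' compartments, a few output/dopaminergic cells per compartment,
#' per-cell-pair Poisson synapse counts, and spatial clustering of
#' convergent KC inputs (convergences, optionally upgraded to rosettes by
#' a KC>KC contact inside the cluster).
#'
#' The lobe is modelled as a cylinder of radius `lobe_radius` whose axis
#' spans three contiguous axial compartments of lengths
#' `compartment_length` (half-open intervals, in axial order a1, a2, a3).
#' KC axons are straight axial lines at a random radial position within
#' `axon_fraction` of the radius; extrinsic innervation covers the full
#' compartment cross-section.
#'
#' @param n_kc Named integer vector of KC counts per subtype. Defaults to
#'   the published subtype census (480 surface, 132 outer core, 259 inner
#'   core, 78 posterior).
#' @param extrinsic Data frame `cell_type`, `compartment`, `n` of
#'   extrinsic cells per compartment.
#' @param wiring Data frame of per-pair Poisson means, as
#'   [default_wiring_rates()].
#' @param lobe_radius Cylinder radius, nm.
#' @param compartment_length Named vector of compartment lengths, nm, in
#'   axial order.
#' @param axon_fraction KC axons are placed within this fraction of the
#'   radius.
#' @param kc_jitter SD (nm) of the lateral scatter of KC presynaptic
#'   sites around the axon line.
#' @param convergence_rate Probability that a KC>MBON contact is placed
#'   into a spatial cluster with other KCs' contacts onto the same MBON.
#' @param rosette_rate Conditional probability that a planted convergence
#'   receives a KC>KC contact between two member KCs (making it a
#'   rosette).
#' @param cluster_radius Members of a planted cluster are placed within a
#'   ball of this radius (nm), so pairwise distances are at most twice
#'   this; the default 140 nm keeps every pair within the 300 nm
#'   convergence criterion.
#' @param cluster_sizes,cluster_size_probs Candidate cluster sizes
#'   (numbers of member contacts) and their probabilities.
#' @param min_cluster_separation When > 0, planted cluster centres on the
#'   same postsynaptic neuron are kept at least this far apart (nm) by
#'   rejection sampling; a geometry too small to honour it is an error.
#' @param seed Integer seed; recorded in the ground truth.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_kc = c("KC-ab-s" = 480L, "KC-ab-c-o" = 132L,
                                      "KC-ab-c-i" = 259L, "KC-ab-p" = 78L),
                             extrinsic = default_extrinsic_census(),
                             wiring = default_wiring_rates(),
                             lobe_radius = 5000,
                             compartment_length = c(a1 = 10000, a2 = 10000,
                                                    a3 = 10000),
                             axon_fraction = 0.85,
                             kc_jitter = 300,
                             convergence_rate = 0.85,
                             rosette_rate = 0.73,
                             cluster_radius = 140,
                             cluster_sizes = c(2L, 3L, 4L),
                             cluster_size_probs = c(0.5, 0.3, 0.2),
                             min_cluster_separation = 0,
                             seed = 1L) {
  stopifnot(all(n_kc >= 0), all(extrinsic$n >= 0),
            all(wiring$lambda >= 0),
            convergence_rate >= 0, convergence_rate <= 1,
            rosette_rate >= 0, rosette_rate <= 1,
            lobe_radius > 0, all(compartment_length > 0),
            length(cluster_sizes) == length(cluster_size_probs),
            all(cluster_sizes >= 2L))
  if (is.null(names(n_kc)) || !all(names(n_kc) %in% kc_subtypes()))
    stop("n_kc must be named by KC subtype token", call. = FALSE)
  structure(
    list(n_kc = n_kc, extrinsic = extrinsic, wiring = wiring,
         lobe_radius = lobe_radius, compartment_length = compartment_length,
         axon_fraction = axon_fraction, kc_jitter = kc_jitter,
         convergence_rate = convergence_rate, rosette_rate = rosette_rate,
         cluster_radius = cluster_radius, cluster_sizes = cluster_sizes,
         cluster_size_probs = cluster_size_probs,
         min_cluster_separation = min_cluster_separation,
         seed = as.integer(seed)),
    class = "generator_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' Fields mirror the arguments of [generator_config()]; missing fields
#' take their defaults. `wiring` and `extrinsic`, when given, are lists of
#' column vectors.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(file) {
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
  args <- list()
  scalar <- c("lobe_radius", "axon_fraction", "kc_jitter",
              "convergence_rate", "rosette_rate", "cluster_radius",
              "min_cluster_separation", "seed")
  for (f in scalar) if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$n_kc)) args$n_kc <- unlist(cfg$n_kc)
  if (!is.null(cfg$compartment_length))
    args$compartment_length <- unlist(cfg$compartment_length)
  if (!is.null(cfg$cluster_sizes)) args$cluster_sizes <- unlist(cfg$cluster_sizes)
  if (!is.null(cfg$cluster_size_probs))
    args$cluster_size_probs <- unlist(cfg$cluster_size_probs)
  if (!is.null(cfg$extrinsic)) args$extrinsic <- as.data.frame(cfg$extrinsic)
  if (!is.null(cfg$wiring)) args$wiring <- as.data.frame(cfg$wiring)
  do.call(generator_config, args)
}

# axial [lo, hi) intervals per compartment, in declared order
compartment_intervals <- function(len) {
  hi <- cumsum(as.numeric(len))
  lo <- c(0, hi[-length(hi)])
  data.frame(compartment = names(len), z_lo = lo, z_hi = hi,
             stringsAsFactors = FALSE)
}

# uniform points in a disk of radius r centred at (cx, cy)
runif_disk <- function(n, r, cx, cy) {
  rad <- r * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = cx + rad * cos(th), y = cy + rad * sin(th))
}

# uniform points in a ball of radius r
runif_ball <- function(n, r) {
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    m <- matrix(stats::runif(3 * 2 * (n - nrow(out) + 4), -r, r), ncol = 3)
    m <- m[rowSums(m^2) <= r^2, , drop = FALSE]
    out <- rbind(out, m)
  }
  out[seq_len(n), , drop = FALSE]
}

# cluster centres in the compartment slab, optionally min_sep apart
place_centers <- function(n, z_lo, z_hi, r_eff, cx, cy, min_sep) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  if (min_sep <= 0) {
    xy <- runif_disk(n, r_eff, cx, cy)
    return(cbind(xy, z = stats::runif(n, z_lo, z_hi)))
  }
  acc <- matrix(NA_real_, n, 3)
  got <- 0L
  tries <- 0L
  max_tries <- 2000L * n
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("geometry too small to place ", n, " clusters at separation ",
           min_sep, " nm", call. = FALSE)
    xy <- runif_disk(1L, r_eff, cx, cy)
    cand <- c(xy[1, 1], xy[1, 2], stats::runif(1, z_lo, z_hi))
    if (got == 0L ||
        min(rowSums(sweep(acc[seq_len(got), , drop = FALSE], 2, cand)^2)) >=
        min_sep^2) {
      got <- got + 1L
      acc[got, ] <- cand
    }
  }
  colnames(acc) <- c("x", "y", "z")
  acc
}

#' Generate a synthetic alpha-lobe connectome with known ground truth
#'
#' For each (presynaptic cell, postsynaptic cell) pair of the configured
#' connection types the synapse count is an independent Poisson draw with
#' the configured per-pair mean; each contact receives its own presynaptic
#' site placed inside the presynaptic cell's compartment span. A fraction
#' of KC>MBON contacts is planted into spatial convergence clusters
#' (members within `cluster_radius` of a common centre, distinct KCs), and
#' a fraction of those clusters receives a KC>KC contact between member
#' KCs, making them rosettes. Identical (config, seed) gives a
#' bit-identical connectome.
#'
#' @param config A [generator_config()].
#' @return List with elements `connectome` (a [connectome()]) and `truth`,
#'   a `ground_truth` list recording the seed, config, all per-pair
#'   Poisson draws (`pair_draws`), planted clusters (`clusters`,
#'   `members`), rosette contacts (`rosette_contacts`) and the realized
#'   per-MBON convergence fraction (`convergence_fraction`).
#' @export
generate_connectome <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  R <- config$lobe_radius
  cx <- cy <- R * 1.5
  iv <- compartment_intervals(config$compartment_length)
  comp_order <- iv$compartment

  # --- neurons ---------------------------------------------------------
  kc_ids <- character(0); kc_types <- character(0)
  for (st in names(config$n_kc)) {
    n <- config$n_kc[[st]]
    if (n > 0) {
      kc_ids <- c(kc_ids, sprintf("%s.%04d", st, seq_len(n)))
      kc_types <- c(kc_types, rep(st, n))
    }
  }
  ex <- config$extrinsic
  ex_ids <- character(0); ex_types <- character(0); ex_comp <- character(0)
  if (nrow(ex)) for (i in seq_len(nrow(ex))) {
    n <- ex$n[i]
    if (n > 0) {
      lab <- if (n <= 26L) LETTERS[seq_len(n)] else sprintf("%03d", seq_len(n))
      ex_ids <- c(ex_ids, paste0(ex$cell_type[i], ".", lab))
      ex_types <- c(ex_types, rep(ex$cell_type[i], n))
      ex_comp <- c(ex_comp, rep(ex$compartment[i], n))
    }
  }
  neurons <- data.frame(
    neuron_id = c(kc_ids, ex_ids),
    cell_type = c(kc_types, ex_types),
    instance_label = c(rep("", length(kc_ids)),
                       sub("^.*\\.", "", ex_ids)),
    stringsAsFactors = FALSE)
  home <- c(rep(NA_character_, length(kc_ids)), ex_comp)
  names(home) <- neurons$neuron_id

  axon_xy <- runif_disk(length(kc_ids), config$axon_fraction * R, cx, cy)
  rownames(axon_xy) <- kc_ids

  # --- per-pair Poisson draws -----------------------------------------
  is_kc_tok <- function(tok) tok == "KC" | tok %in% kc_subtypes()
  cells_of <- function(tok, comp) {
    if (tok == "KC") return(kc_ids)
    if (tok %in% kc_subtypes()) return(kc_ids[kc_types == tok])
    ids <- ex_ids[ex_types == tok & ex_comp == comp]
    ids
  }
  draws <- vector("list", nrow(config$wiring))
  for (i in seq_len(nrow(config$wiring))) {
    w <- config$wiring[i, ]
    pre <- cells_of(w$pre_type, w$compartment)
    post <- cells_of(w$post_type, w$compartment)
    if (!length(pre) || !length(post) || w$lambda <= 0) next
    g <- expand.grid(pre_neuron = pre, post_neuron = post,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$n <- stats::rpois(nrow(g), w$lambda)
    g$pre_type <- w$pre_type; g$post_type <- w$post_type
    g$compartment <- w$compartment; g$lambda <- w$lambda
    draws[[i]] <- g
  }
  draws <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  if (is.null(draws))
    draws <- data.frame(pre_neuron = character(0), post_neuron = character(0),
                        n = integer(0), pre_type = character(0),
                        post_type = character(0), compartment = character(0),
                        lambda = numeric(0))

  # --- expand to contacts, default site placement ---------------------
  nc <- sum(draws$n)
  if (nc > 0) {
    ridx <- rep.int(seq_len(nrow(draws)), draws$n)
    con <- data.frame(pre_neuron = draws$pre_neuron[ridx],
                      post_neuron = draws$post_neuron[ridx],
                      compartment = draws$compartment[ridx],
                      pre_is_kc = is_kc_tok(draws$pre_type)[ridx],
                      post_is_mbon = grepl("^MBON", draws$post_type)[ridx],
                      stringsAsFactors = FALSE)
    zi <- match(con$compartment, iv$compartment)
    con$z <- stats::runif(nc, iv$z_lo[zi], iv$z_hi[zi])
    kc_rows <- which(con$pre_is_kc)
    ex_rows <- which(!con$pre_is_kc)
    con$x <- NA_real_; con$y <- NA_real_
    if (length(kc_rows)) {
      ai <- match(con$pre_neuron[kc_rows], kc_ids)
      con$x[kc_rows] <- pmax(0, axon_xy[ai, 1] +
                               stats::rnorm(length(kc_rows), 0, config$kc_jitter))
      con$y[kc_rows] <- pmax(0, axon_xy[ai, 2] +
                               stats::rnorm(length(kc_rows), 0, config$kc_jitter))
    }
    if (length(ex_rows)) {
      xy <- runif_disk(length(ex_rows), R, cx, cy)
      con$x[ex_rows] <- xy[, 1]; con$y[ex_rows] <- xy[, 2]
    }
  } else {
    con <- data.frame(pre_neuron = character(0), post_neuron = character(0),
                      compartment = character(0), pre_is_kc = logical(0),
                      post_is_mbon = logical(0), z = numeric(0),
                      x = numeric(0), y = numeric(0))
  }
  con$site_id <- sprintf("s%07d", seq_len(nrow(con)))

  # --- convergence planting (KC>MBON contacts per MBON) ---------------
  clusters <- list(); members <- list(); rosettes <- list()
  conv_frac <- list()
  cl_counter <- 0L
  kcmbon_idx <- which(con$pre_is_kc & con$post_is_mbon)
  for (mbon in unique(con$post_neuron[kcmbon_idx])) {
    rows <- kcmbon_idx[con$post_neuron[kcmbon_idx] == mbon]
    pick <- rows[stats::runif(length(rows)) < config$convergence_rate]
    pick <- pick[sample.int(length(pick))]
    # greedy grouping into clusters of distinct presynaptic KCs
    groups <- list()
    pool <- pick
    while (length(pool) >= 2L) {
      sz <- sample(config$cluster_sizes, 1L, prob = config$cluster_size_probs)
      sz <- min(sz, length(pool))
      take <- integer(0); seen <- character(0)
      for (j in seq_along(pool)) {
        kc <- con$pre_neuron[pool[j]]
        if (!(kc %in% seen)) {
          take <- c(take, j); seen <- c(seen, kc)
          if (length(take) == sz) break
        }
      }
      if (length(take) < 2L) break
      groups[[length(groups) + 1L]] <- pool[take]
      pool <- pool[-take]
    }
    if (length(groups)) {
      comp <- con$compartment[groups[[1]][1]]
      zi <- match(comp, iv$compartment)
      r_eff <- max(R - config$cluster_radius, 0.5 * R)
      ctr <- place_centers(length(groups), iv$z_lo[zi], iv$z_hi[zi],
                           r_eff, cx, cy, config$min_cluster_separation)
      for (gi in seq_along(groups)) {
        cl_counter <- cl_counter + 1L
        g <- groups[[gi]]
        off <- runif_ball(length(g), config$cluster_radius)
        con$x[g] <- pmax(0, ctr[gi, 1] + off[, 1])
        con$y[g] <- pmax(0, ctr[gi, 2] + off[, 2])
        con$z[g] <- pmin(pmax(ctr[gi, 3] + off[, 3], iv$z_lo[zi]),
                         iv$z_hi[zi] - 1e-6)
        is_ros <- stats::runif(1) < config$rosette_rate
        clusters[[cl_counter]] <- data.frame(
          cluster_id = cl_counter, post_neuron = mbon, compartment = comp,
          size = length(g), is_rosette = is_ros)
        members[[cl_counter]] <- data.frame(
          cluster_id = cl_counter, site_id = con$site_id[g],
          pre_neuron = con$pre_neuron[g])
        if (is_ros) {
          pair <- sample(unique(con$pre_neuron[g]), 2L)
          host <- g[con$pre_neuron[g] == pair[1]][1]
          rosettes[[length(rosettes) + 1L]] <- data.frame(
            cluster_id = cl_counter, site_id = con$site_id[host],
            pre_kc = pair[1], post_kc = pair[2])
        }
      }
    }
    n_in <- sum(vapply(groups, length, integer(1)))
    conv_frac[[mbon]] <- data.frame(post_neuron = mbon,
                                    n_sites = length(rows),
                                    n_in_cluster = n_in,
                                    fraction = n_in / max(length(rows), 1L))
  }
  bindl <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  clusters <- bindl(clusters, data.frame(cluster_id = integer(0),
                                         post_neuron = character(0),
                                         compartment = character(0),
                                         size = integer(0),
                                         is_rosette = logical(0)))
  members <- bindl(members, data.frame(cluster_id = integer(0),
                                       site_id = character(0),
                                       pre_neuron = character(0)))
  rosettes <- bindl(rosettes, data.frame(cluster_id = integer(0),
                                         site_id = character(0),
                                         pre_kc = character(0),
                                         post_kc = character(0)))
  conv_frac <- bindl(unname(conv_frac),
                     data.frame(post_neuron = character(0),
                                n_sites = integer(0),
                                n_in_cluster = integer(0),
                                fraction = numeric(0)))

  # --- assemble -------------------------------------------------------
  sites <- data.frame(site_id = con$site_id, pre_neuron = con$pre_neuron,
                      x = con$x, y = con$y, z = con$z,
                      compartment = con$compartment,
                      stringsAsFactors = FALSE)
  contacts <- data.frame(site_id = con$site_id, post_neuron = con$post_neuron,
                         stringsAsFactors = FALSE)
  if (nrow(rosettes))
    contacts <- rbind(contacts,
                      data.frame(site_id = rosettes$site_id,
                                 post_neuron = rosettes$post_kc))
  x <- connectome(neurons, sites, contacts, compartment_order = comp_order)
  truth <- structure(
    list(seed = config$seed, config = config,
         pair_draws = draws[, c("pre_neuron", "post_neuron", "pre_type",
                                "post_type", "compartment", "lambda", "n")],
         clusters = clusters, members = members,
         rosette_contacts = rosettes,
         convergence_fraction = conv_frac),
    class = "ground_truth")
  list(connectome = x, truth = truth)
}

#' Plant two same-type cells wiring independently onto the KC population
#'
#' Builds a minimal connectome in which each KC connects to cell A with
#' probability `p_a` and, independently, to cell B with probability `p_b`
#' (one synapse per connection). This is the simulated null for the
#' shared-partner independence analysis.
#'
#' @param n_kc Number of candidate KCs.
#' @param p_a,p_b Per-KC connection probabilities of the two cells.
#' @param seed Integer seed.
#' @return A [connectome()] with cells `PPL1-ap2a2.A` / `PPL1-ap2a2.B`
#'   presynaptic to KCs in compartment a2.
#' @export
plant_null_independent_pair <- function(n_kc = 949L, p_a = 0.5, p_b = 0.5,
                                        seed = 1L) {
  stopifnot(n_kc >= 1, p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1)
  set.seed(as.integer(seed))
  kcs <- sprintf("KC-ab-s.%04d", seq_len(n_kc))
  dans <- c("PPL1-ap2a2.A", "PPL1-ap2a2.B")
  neurons <- data.frame(
    neuron_id = c(kcs, dans),
    cell_type = c(rep("KC-ab-s", n_kc), rep("PPL1-ap2a2", 2L)),
    instance_label = c(rep("", n_kc), "A", "B"))
  hit_a <- stats::runif(n_kc) < p_a
  hit_b <- stats::runif(n_kc) < p_b
  pre <- c(rep(dans[1], sum(hit_a)), rep(dans[2], sum(hit_b)))
  post <- c(kcs[hit_a], kcs[hit_b])
  n <- length(pre)
  sites <- data.frame(site_id = sprintf("s%06d", seq_len(n)),
                      pre_neuron = pre,
                      x = stats::runif(n, 0, 10000),
                      y = stats::runif(n, 0, 10000),
                      z = stats::runif(n, 10000, 20000),
                      compartment = "a2")
  contacts <- data.frame(site_id = sites$site_id, post_neuron = post)
  connectome(neurons, sites, contacts)
}
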