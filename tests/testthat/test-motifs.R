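# helper: a hand-built scene of KC sites around one MBON
scene <- function(site_xyz, kc_of_site, extra_sites = NULL,
                  extra_contacts = NULL) {
  n <- nrow(site_xyz)
  s <- data.frame(site_id = sprintf("s%d", seq_len(n)),
                  pre_neuron = kc_of_site,
                  x = site_xyz[, 1], y = site_xyz[, 2], z = site_xyz[, 3],
                  compartment = "a3")
  cc <- data.frame(site_id = s$site_id, post_neuron = "MBON-a3.A")
  if (!is.null(extra_sites)) s <- rbind(s, extra_sites)
  if (!is.null(extra_contacts)) cc <- rbind(cc, extra_contacts)
  build_connectome(s, cc)
}

test_that("convergences require two KCs within the radius on a common target", {
  near <- scene(rbind(c(0, 0, 0), c(200, 0, 0)),
                c("KC-ab-s.1", "KC-ab-s.2"))
  cl <- find_convergences(near, "MBON", 300)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_setequal(cl$pre_neuron, c("KC-ab-s.1", "KC-ab-s.2"))

  far <- scene(rbind(c(0, 0, 0), c(500, 0, 0)),
               c("KC-ab-s.1", "KC-ab-s.2"))
  expect_equal(nrow(find_convergences(far, "MBON", 300)), 0L)

  # two sites of the same KC are not a convergence
  same <- scene(rbind(c(0, 0, 0), c(100, 0, 0)),
                c("KC-ab-s.1", "KC-ab-s.1"))
  expect_equal(nrow(find_convergences(same, "MBON", 300)), 0L)

  # ties at exactly the threshold count as within (closed ball)
  tie <- scene(rbind(c(0, 0, 0), c(300, 0, 0)),
               c("KC-ab-s.1", "KC-ab-s.2"))
  expect_equal(length(unique(find_convergences(tie, "MBON", 300)$cluster_id)),
               1L)
})

test_that("rosette status needs a member-KC to member-KC contact inside the cluster", {
  base_xyz <- rbind(c(0, 0, 0), c(200, 0, 0))
  kcs <- c("KC-ab-s.1", "KC-ab-s.2")

  # KC>KC contact between members, at a member site: rosette
  x1 <- scene(base_xyz, kcs,
              extra_contacts = data.frame(site_id = "s1",
                                          post_neuron = "KC-ab-s.2"))
  cl1 <- find_rosettes(find_convergences(x1, "MBON", 300), x1)
  expect_true(all(attr(cl1, "is_rosette")))

  # KC>KC contact between non-members (elsewhere): not a rosette
  x2 <- scene(base_xyz, kcs,
              extra_sites = site_row("s9", "KC-ab-s.3", 9000, 9000, 9000, "a3"),
              extra_contacts = data.frame(site_id = "s9",
                                          post_neuron = "KC-ab-s.4"))
  cl2 <- find_rosettes(find_convergences(x2, "MBON", 300), x2)
  expect_false(any(attr(cl2, "is_rosette")))

  # member-to-member contact but released far from the cluster: not a rosette
  x3 <- scene(base_xyz, kcs,
              extra_sites = site_row("s9", "KC-ab-s.1", 8000, 8000, 8000, "a3"),
              extra_contacts = data.frame(site_id = "s9",
                                          post_neuron = "KC-ab-s.2"))
  cl3 <- find_rosettes(find_convergences(x3, "MBON", 300), x3)
  expect_false(any(attr(cl3, "is_rosette")))
})

test_that("motif fractions cover the all-isolated and all-rosette extremes", {
  iso <- scene(rbind(c(0, 0, 0), c(5000, 0, 0), c(0, 5000, 0)),
               c("KC-ab-s.1", "KC-ab-s.2", "KC-ab-s.3"))
  mf <- motif_fractions(iso, "MBON")
  expect_equal(mf$percent_in_convergence, 0)
  expect_equal(mf$percent_in_rosette, 0)

  ros <- scene(rbind(c(0, 0, 0), c(150, 0, 0)),
               c("KC-ab-s.1", "KC-ab-s.2"),
               extra_contacts = data.frame(site_id = "s1",
                                           post_neuron = "KC-ab-s.2"))
  mf <- motif_fractions(ros, "MBON")
  expect_equal(mf$percent_in_convergence, 100)
  expect_equal(mf$percent_in_rosette, 100)
})

test_that("single-linkage clustering matches the hclust oracle on random scenes", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 40L
    xyz <- cbind(runif(n, 0, 3000), runif(n, 0, 3000), runif(n, 0, 3000))
    kcs <- sprintf("KC-ab-s.%d", seq_len(n)) # all-distinct KCs
    x <- scene(xyz, kcs)
    cl <- find_convergences(x, "MBON", 300)

    oracle <- oracle_single_linkage(xyz, 300)
    keep <- oracle %in% names(which(table(oracle) >= 2))
    sig_oracle <- partition_signature(sprintf("s%d", which(keep)),
                                      oracle[keep])
    sig_pkg <- partition_signature(cl$site_id, cl$cluster_id)
    expect_equal(sig_pkg, sig_oracle)
  }
})

test_that("detection is invariant to site order and rigid motion", {
  set.seed(4)
  n <- 30L
  xyz <- cbind(runif(n, 0, 2000), runif(n, 0, 2000), runif(n, 0, 2000))
  kcs <- sprintf("KC-ab-s.%d", sample(1:12, n, replace = TRUE))
  x <- scene(xyz, kcs)
  sig1 <- partition_signature(
    find_convergences(x, "MBON", 300)$site_id,
    find_convergences(x, "MBON", 300)$cluster_id)

  # permute site order
  perm <- sample.int(n)
  xp <- scene(xyz[perm, ], kcs[perm])
  clp <- find_convergences(xp, "MBON", 300)
  # site ids were reassigned by position; map back through coordinates
  key <- function(cl, xx) {
    m <- match(cl$site_id, xx$sites$site_id)
    sprintf("%.3f,%.3f,%.3f", xx$sites$x[m], xx$sites$y[m], xx$sites$z[m])
  }
  expect_equal(partition_signature(key(clp, xp), clp$cluster_id),
               partition_signature(key(find_convergences(x, "MBON", 300), x),
                                   find_convergences(x, "MBON", 300)$cluster_id))

  # rotate about z and translate
  th <- 0.83
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz_r <- sweep(xyz %*% Rz, 2, c(4000, 5000, 6000), "+")
  xr <- scene(xyz_r, kcs)
  clr <- find_convergences(xr, "MBON", 300)
  expect_equal(length(unique(clr$cluster_id)),
               length(unique(find_convergences(x, "MBON", 300)$cluster_id)))
  expect_equal(sort(table(clr$cluster_id)),
               sort(table(find_convergences(x, "MBON", 300)$cluster_id)),
               ignore_attr = TRUE)
})

test_that("planted convergences and rosettes are recovered perfectly when separated", {
  cfg <- small_config(seed = 55L, n_s = 20L, lambda = 3, convergence_rate = 1,
                      rosette_rate = 0.6, min_sep = 900)
  gen <- generate_connectome(cfg)
  x <- gen$connectome
  tr <- gen$truth
  cl <- find_rosettes(find_convergences(x, "MBON", 300), x)

  sig_truth <- partition_signature(tr$members$site_id, tr$members$cluster_id)
  sig_found <- partition_signature(cl$site_id, cl$cluster_id)
  expect_equal(sig_found, sig_truth) # 100% precision and recall

  # rosette flags agree cluster by cluster
  found_ros <- attr(cl, "is_rosette")
  sig_of <- function(ids, groups) {
    vapply(split(ids, groups), function(k) paste(sort(k), collapse = "|"),
           character(1))
  }
  truth_sig <- sig_of(tr$members$site_id, tr$members$cluster_id)
  found_sig <- sig_of(cl$site_id, cl$cluster_id)
  truth_ros <- tr$clusters$is_rosette[
    match(names(truth_sig), as.character(tr$clusters$cluster_id))]
  m <- match(found_sig, truth_sig)
  expect_false(anyNA(m))
  expect_equal(unname(found_ros[names(found_sig)]), truth_ros[m])
})

test_that("triangle motifs match exhaustive enumeration on a random toy", {
  set.seed(66)
  n_kc <- 12L; n_sites <- 40L
  kcs <- sprintf("KC-ab-s.%d", 1:n_kc)
  xyz <- cbind(runif(n_sites, 0, 2500), runif(n_sites, 0, 2500),
               runif(n_sites, 0, 2500))
  s <- data.frame(site_id = sprintf("s%d", 1:n_sites),
                  pre_neuron = sample(kcs, n_sites, replace = TRUE),
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  compartment = "a3")
  cc <- data.frame(site_id = s$site_id,
                   post_neuron = sample(c("MBON-a3.A", "MBON-a3.B"),
                                        n_sites, replace = TRUE))
  # sprinkle KC>KC contacts
  kk_host <- sample(s$site_id, 10L)
  kk_post <- sample(kcs, 10L, replace = TRUE)
  keep <- s$pre_neuron[match(kk_host, s$site_id)] != kk_post
  cc <- rbind(cc, data.frame(site_id = kk_host[keep],
                             post_neuron = kk_post[keep]))
  cc <- cc[!duplicated(paste(cc$site_id, cc$post_neuron)), ]
  x <- build_connectome(s, cc)

  cl <- find_convergences(x, "MBON", 300)
  tri <- triangle_motifs(x, clusters = cl)

  # oracle: direct definition over all (pair, mbon, cluster) combinations
  ct <- merge(x$contacts, x$sites, by = "site_id")
  kk <- ct[grepl("^KC", ct$pre_neuron) & grepl("^KC", ct$post_neuron) &
             ct$pre_neuron != ct$post_neuron, ]
  kk_keys <- unique(paste(pmin(kk$pre_neuron, kk$post_neuron),
                          pmax(kk$pre_neuron, kk$post_neuron)))
  expected <- character(0)
  for (cid in unique(cl$cluster_id)) {
    mem <- cl[cl$cluster_id == cid, ]
    mk <- sort(unique(mem$pre_neuron))
    if (length(mk) < 2) next
    prs <- t(combn(mk, 2))
    for (i in seq_len(nrow(prs)))
      if (paste(prs[i, 1], prs[i, 2]) %in% kk_keys)
        expected <- c(expected,
                      paste(prs[i, 1], prs[i, 2], mem$post_neuron[1]))
  }
  expect_setequal(paste(tri$kc_a, tri$kc_b, tri$mbon), unique(expected))

  # no KC>KC contacts anywhere: empty result
  x0 <- build_connectome(s, cc[grepl("^MBON", cc$post_neuron), ])
  expect_equal(nrow(triangle_motifs(x0)), 0L)
})

test_that("a two-KC rosette yields exactly one triangle", {
  x <- scene(rbind(c(0, 0, 0), c(150, 0, 0)),
             c("KC-ab-s.1", "KC-ab-s.2"),
             extra_contacts = data.frame(site_id = "s1",
                                         post_neuron = "KC-ab-s.2"))
  tri <- triangle_motifs(x)
  expect_equal(nrow(tri), 1L)
  expect_setequal(c(tri$kc_a, tri$kc_b), c("KC-ab-s.1", "KC-ab-s.2"))
  expect_equal(tri$mbon, "MBON-a3.A")
})
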