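test_that("torsion extraction recovers planted backbone and chi1 angles", {
  pep <- build_peptide(phi = rep(-57, 6), psi = rep(-47, 6),
                       chi1 = c(-60, 180, 60, -60, 180, 60))
  tor <- extract_torsions(static_traj(pep, 2))
  for (i in 2:5) {
    expect_equal(tor$series[[paste0("A:", i, "|phi")]][1], -57,
                 tolerance = 1e-6)
    expect_equal(tor$series[[paste0("A:", i, "|psi")]][1], -47,
                 tolerance = 1e-6)
  }
  # planted 180 reports as -180 under the [-180, 180) wrap convention
  expect_equal(abs(tor$series[["A:2|chi1"]][1]), 180, tolerance = 1e-6)
  expect_equal(tor$series[["A:4|chi1"]][1], -60, tolerance = 1e-6)
  # chi2 atoms (CD1) are absent -> skipped with a log entry, never NaN
  expect_true(any(grepl("chi2", attr(tor, "skipped"))))
  expect_false(any(vapply(tor$series, anyNA, logical(1))))
  # glycine emits no chi series
  gly <- build_peptide(phi = rep(-57, 4), psi = rep(-47, 4))
  tg <- extract_torsions(static_traj(gly, 2))
  expect_false(any(grepl("chi", names(tg$series))))
})

test_that("plug-in MI matches hand evaluation and analytic limits", {
  # binary joint counts [[40,10],[10,40]] -> 0.1927 nats
  counts <- matrix(c(40, 10, 10, 40), 2, 2)
  s <- series_from_counts(counts)
  expect_equal(torsion_mi(s$x, s$y), oracle_mi_from_counts(counts),
               tolerance = 1e-12)
  expect_equal(torsion_mi(s$x, s$y), 0.1927, tolerance = 1e-3)
  # perfectly co-switching two-state series, equal occupancy -> ln 2
  n <- 1e4
  st <- rep(c(0L, 1L), each = n / 2)
  x <- ifelse(st == 0, -60, 180)
  expect_equal(torsion_mi(x, x), log(2), tolerance = 1e-12)
  # symmetry
  set.seed(11)
  a <- runif(500, -180, 180); b <- runif(500, -180, 180)
  expect_equal(torsion_mi(a, b), torsion_mi(b, a), tolerance = 1e-12)
  expect_error(torsion_mi(a, b[-1]), "length mismatch")
  # Miller-Madow correction shifts by the analytic first-order bias
  mi0 <- torsion_mi(a, b)
  mic <- torsion_mi(a, b, correction = TRUE)
  expect_lt(mic, mi0)
})

test_that("shuffling one series of a correlated pair destroys MI", {
  sys <- generate_torsion_system(torsion_system_spec(
    n_residues = 4, n_frames = 4000, relay = 1:2, coupling = 1, seed = 8))
  x <- sys$torsions$series[["A:1|chi1"]]
  y <- sys$torsions$series[["A:2|chi1"]]
  expect_gt(torsion_mi(x, y), 0.5)
  set.seed(99)
  expect_lt(torsion_mi(x, sample(y)), 23^2 / (2 * 4000))
})

test_that("residue MI matrix equals a brute-force torsion-pair loop", {
  sys <- generate_torsion_system(torsion_system_spec(
    n_residues = 5, n_frames = 600, relay = 1:3, coupling = 0.8, seed = 5))
  # add a second torsion to residues 1 and 2 so aggregation matters
  ts <- sys$torsions
  set.seed(6)
  ts$series[["A:1|phi"]] <- runif(600, -180, 180)
  ts$series[["A:2|phi"]] <- runif(600, -180, 180)
  mi <- residue_mi_matrix(ts, aggregation = "max", min_seq_sep = 3)
  mis <- residue_mi_matrix(ts, aggregation = "sum", min_seq_sep = 3)
  keys <- ts$residues
  by_res <- lapply(keys, function(k)
    ts$series[grep(paste0("^", k, "\\|"), names(ts$series))])
  for (i in 1:4) for (j in (i + 1):5) {
    vals <- c()
    for (a in by_res[[i]]) for (b in by_res[[j]])
      vals <- c(vals, torsion_mi(a, b))
    expect_equal(mi$mi[i, j], max(vals), tolerance = 1e-12)
    expect_equal(mis$mi[i, j], sum(vals), tolerance = 1e-12)
    expect_equal(mi$mi[i, j], mi$mi[j, i])
  }
  # |i-j| < 3 on one chain is ineligible but still reported
  expect_false(mi$eligible[1, 2])
  expect_true(mi$eligible[1, 4])
  expect_false(is.na(mi$mi[1, 2]))
})

test_that("graph construction keeps the top decile with tie expansion", {
  # 10 eligible pairs, MI 1..10 -> exactly the MI=10 edge
  m <- matrix(0, 5, 5)
  vals <- 1:10
  k <- 0
  for (i in 1:4) for (j in (i + 1):5) { k <- k + 1; m[i, j] <- m[j, i] <- vals[k] }
  mi <- as_mi_matrix(m, paste0("A:", 1:5))
  g <- build_graph(mi, 0.10)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$mi, 10)
  expect_equal(g$edges$weight, 0)  # -ln(MI/MI_max) at the max
  # all pairs equal -> all tie at threshold -> all retained
  me <- as_mi_matrix(matrix(1, 5, 5), paste0("A:", 1:5))
  expect_equal(nrow(build_graph(me, 0.10)$edges), 10)
  # 200 random values: edge set equals sort-and-slice with tie expansion
  set.seed(17)
  n <- 21  # 210 pairs
  r <- matrix(0, n, n)
  vals <- sample(round(runif(n * (n - 1) / 2, 0, 1), 2))  # forces ties
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- k + 1; r[i, j] <- r[j, i] <- vals[k]
  }
  gr <- build_graph(as_mi_matrix(r, paste0("A:", 1:n)), 0.10)
  thr <- sort(vals, decreasing = TRUE)[ceiling(0.10 * length(vals))]
  expect_equal(nrow(gr$edges), sum(vals >= thr))
  expect_true(all(gr$edges$mi >= thr))
  expect_true(all(gr$edges$weight >= 0))
  # all-zero MI is an explicit empty-graph error
  expect_error(build_graph(as_mi_matrix(matrix(0, 3, 3), paste0("A:", 1:3))),
               "empty")
})

test_that("pathways respect the >10 A separation rule", {
  m <- matrix(0, 2, 2); m[1, 2] <- m[2, 1] <- 1
  mi <- as_mi_matrix(m, c("A:1", "A:2"))
  g <- build_graph(mi, 1)
  near <- point_model(matrix(c(0, 0, 0, 8, 0, 0), 2, 3, byrow = TRUE))
  far <- point_model(matrix(c(0, 0, 0, 12, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(length(allosteric_paths(g, "A:1", near)), 0)
  p <- allosteric_paths(g, "A:1", far)
  expect_equal(length(p), 1)
  expect_equal(p[[1]]$residues, c("A:1", "A:2"))
  expect_equal(p[[1]]$separation, 12)
  expect_error(allosteric_paths(g, character(0), far), "empty source")
})

test_that("Dijkstra pathways equal exhaustive enumeration on random graphs", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    keys <- paste0("A:", 1:n)
    m <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.6) m[i, j] <- m[j, i] <- runif(1, 0.1, 1)
    if (max(m) == 0) next
    mi <- as_mi_matrix(m, keys)
    g <- build_graph(mi, 1)  # keep all positive-MI edges
    coords <- matrix(rnorm(3 * n, sd = 30), n, 3)
    mod <- point_model(coords)
    paths <- allosteric_paths(g, keys[1], mod)
    for (p in paths) {
      want <- oracle_min_path_weight(g$edges, p$source, p$sink)
      expect_equal(p$weight, want, tolerance = 1e-9)
      # consecutive residues are graph edges; no repeats
      expect_false(anyDuplicated(p$residues) > 0)
      ek <- paste(pmin(head(p$residues, -1), tail(p$residues, -1)),
                  pmax(head(p$residues, -1), tail(p$residues, -1)))
      expect_true(all(ek %in% paste(pmin(g$edges$a, g$edges$b),
                                    pmax(g$edges$a, g$edges$b))))
    }
  }
})

test_that("pipeline clustering follows planted geometry and the oracle", {
  n <- 12
  coords <- rbind(cbind(seq(0, 15, length.out = 6), 0, 0),
                  cbind(seq(0, 15, length.out = 6), 40, 0))
  mod <- point_model(coords)
  keys <- mod$residues$reskey
  mkpath <- function(res) structure(list(residues = res, weight = 1,
                                         mi_total = 1, source = res[1],
                                         sink = res[length(res)],
                                         separation = 15),
                                    class = "pathway")
  # two identical pathways -> one pipeline of population 2
  p <- list(mkpath(keys[1:3]), mkpath(keys[1:3]))
  pp <- cluster_pipelines(p, mod)
  expect_equal(length(pp), 1)
  expect_equal(pp[[1]]$population, 2)
  # opposite faces (> 20 A apart) -> two pipelines
  p2 <- list(mkpath(keys[1:3]), mkpath(keys[7:9]))
  expect_equal(length(cluster_pipelines(p2, mod)), 2)
  # 12 pathways in two planted bundles equal single-linkage by construction
  set.seed(31)
  paths <- c(lapply(1:7, function(i) mkpath(keys[sort(sample(1:6, 3))])),
             lapply(1:5, function(i) mkpath(keys[sort(sample(7:12, 3))])))
  pp3 <- cluster_pipelines(paths, mod)
  expect_equal(length(pp3), 2)
  expect_equal(pp3[[1]]$population, 7)  # ranked by population
  expect_equal(sort(unlist(lapply(pp3, `[[`, "members"))), 1:12)
  expect_true(pp3[[1]]$representative %in% pp3[[1]]$members)
})

test_that("hub scores tally pathways and conserve total length", {
  expect_equal(sum(hub_scores(list())$hub), 0)
  mk <- function(res) structure(list(residues = res), class = "pathway")
  p <- list(mk(c("A:1", "A:2", "A:5")), mk(c("A:2", "A:5")),
            mk(c("A:5", "A:9")))
  h <- hub_scores(p)
  expect_equal(h$hub[h$residue == "A:5"], 3)
  expect_equal(h$hub[h$residue == "A:1"], 1)
  expect_equal(sum(h$hub), sum(vapply(p, function(q) length(q$residues),
                                      integer(1))))
  # random pathway sets: conservation + brute-force tally
  set.seed(41)
  for (rep in 1:5) {
    paths <- lapply(1:10, function(i)
      mk(paste0("A:", sample(1:20, sample(2:6, 1)))))
    h <- hub_scores(paths)
    tal <- table(unlist(lapply(paths, `[[`, "residues")))
    expect_equal(sum(h$hub), sum(vapply(paths, function(q)
      length(q$residues), integer(1))))
    for (r in names(tal))
      expect_equal(h$hub[h$residue == r], as.integer(tal[[r]]))
  }
})
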