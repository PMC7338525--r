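fixture <- function(name) system.file("extdata", name, package = "nmrdyn")

test_that("CNS/XPLOR distance restraint tables parse with bounds and groups intact", {
  rs <- parse_distance_restraints(fixture("example_distance.tbl"))
  expect_length(rs, 3)
  # assign d dminus dplus -> [d - dminus, d + dplus]
  expect_equal(rs[[1]]$lower, 2.0)
  expect_equal(rs[[1]]$upper, 4.0)
  expect_equal(rs[[1]]$group_a$resno, 3)
  expect_equal(rs[[1]]$group_a$atom, "HA")
  expect_equal(rs[[2]]$lower, 1.8)
  expect_equal(rs[[2]]$upper, 3.5)
  # ambiguous OR group retained as a two-atom group
  expect_equal(nrow(rs[[3]]$group_a), 2)
  expect_setequal(rs[[3]]$group_a$atom, c("HB1", "HB2"))
  expect_equal(rs[[3]]$group_b$resno, 14)

  empty <- tempfile(fileext = ".tbl")
  writeLines("! nothing here", empty)
  expect_length(parse_distance_restraints(empty), 0)

  bad <- tempfile(fileext = ".tbl")
  writeLines(c("assign (resid 1 and name H) (resid 2 and name H) 3.0 1.0 1.0",
               "assign (resid 3 and name H) 2.0"), bad)
  expect_error(parse_distance_restraints(bad), "line 2")
})

test_that("NMR-STAR distance-constraint loops parse, grouping ambiguous members by ID", {
  rs <- parse_distance_restraints(fixture("example_distance.str"))
  expect_length(rs, 3)
  expect_equal(rs[[1]]$upper, 4.4)
  expect_equal(rs[[1]]$lower, 1.8)
  amb <- rs[[3]]
  expect_equal(nrow(amb$group_a), 2)
  expect_setequal(amb$group_a$atom, c("HB1", "HB2"))
  expect_equal(amb$upper, 5.5)
})

test_that("dihedral restraint tables parse target and range", {
  rs <- parse_dihedral_restraints(fixture("example_dihedral.tbl"))
  expect_length(rs, 2)
  expect_equal(rs[[1]]$target, -57)
  expect_equal(rs[[1]]$range, 20)
  expect_equal(nrow(rs[[1]]$atoms), 4)
  expect_equal(rs[[2]]$atoms$resno, c(5, 5, 5, 6))
})

test_that("sequence-separation classes partition the restraint set", {
  set.seed(9)
  rs <- lapply(1:40, function(i) {
    ra <- sample(1:20, 1); rb <- sample(1:20, 1)
    distance_restraint(data.frame(resno = ra, atom = "H"),
                       data.frame(resno = rb, atom = "HA"),
                       0, 5)
  })
  cl <- classify_distance_restraints(rs)
  expect_equal(sum(cl$counts[c("intraresidue", "sequential", "medium",
                               "long")]),
               unname(cl$counts["total"]))
  # oracle: direct per-pair loop
  want <- vapply(rs, function(r) {
    s <- abs(r$group_a$resno - r$group_b$resno)
    c("intraresidue", "sequential", "medium", "long")[
      findInterval(s, c(0, 1, 2, 5)) ]
  }, character(1))
  expect_identical(cl$class, want)
  # ambiguous restraints use the minimum separation over member pairs
  amb <- distance_restraint(data.frame(resno = c(2, 9), atom = c("H", "H")),
                            data.frame(resno = 10, atom = "HA"), 0, 5)
  expect_equal(classify_distance_restraints(list(amb))$class, "sequential")
})

test_that("r^-6 effective distances obey plain-distance, dominance and monotonicity laws", {
  atoms <- data.frame(chain = "A", resno = c(1, 1, 2, 2),
                      resname = "ALA", atom = c("HB1", "HB2", "H", "HA"))
  xyz <- matrix(c(0, 0, 0,   1, 0, 0,   0, 3, 0,   1, 4, 0),
                4, 3, byrow = TRUE)
  ens <- structure_ensemble(atoms, list(xyz))

  single <- distance_restraint(data.frame(resno = 1, atom = "HB1"),
                               data.frame(resno = 2, atom = "H"), 0, 9)
  expect_equal(effective_distance_r6(ens, 1, single), 3)

  both <- distance_restraint(
    data.frame(resno = c(1, 1), atom = c("HB1", "HB2")),
    data.frame(resno = c(2, 2), atom = c("H", "HA")), 0, 9)
  d <- effective_distance_r6(ens, 1, both)
  # oracle: direct arithmetic over the four cross pairs
  ds <- c(sqrt(sum((xyz[1, ] - xyz[3, ])^2)),
          sqrt(sum((xyz[1, ] - xyz[4, ])^2)),
          sqrt(sum((xyz[2, ] - xyz[3, ])^2)),
          sqrt(sum((xyz[2, ] - xyz[4, ])^2)))
  expect_equal(d, sum(ds^-6)^(-1 / 6), tolerance = 1e-12)
  expect_lte(d, min(ds))

  # adding atoms to a group can only shrink d_eff
  grow <- distance_restraint(
    data.frame(resno = c(1, 1), atom = c("HB1", "HB2")),
    data.frame(resno = 2, atom = "H"), 0, 9)
  expect_lte(effective_distance_r6(ens, 1, grow),
             effective_distance_r6(ens, 1, single) + 1e-12)

  # pseudoatom wildcard expands by prefix
  pseudo <- distance_restraint(data.frame(resno = 1, atom = "HB#"),
                               data.frame(resno = 2, atom = "H"), 0, 9)
  expect_equal(effective_distance_r6(ens, 1, pseudo),
               effective_distance_r6(ens, 1, grow), tolerance = 1e-12)

  missing <- distance_restraint(data.frame(resno = 1, atom = "HG1"),
                                data.frame(resno = 2, atom = "H"), 0, 9)
  expect_error(effective_distance_r6(ens, 1, missing), "HG1")
})

test_that("violations follow max(0, d - upper, lower - d) with r^-6 averaging", {
  atoms <- data.frame(chain = "A", resno = c(1, 2),
                      resname = "ALA", atom = c("HA", "HA"))
  ens <- structure_ensemble(atoms, list(
    matrix(c(0, 0, 0, 3.7, 0, 0), 2, 3, byrow = TRUE)))
  stretched <- distance_restraint(data.frame(resno = 1, atom = "HA"),
                                  data.frame(resno = 2, atom = "HA"), 0, 3.0)
  rep <- violation_report(ens, list(stretched))
  expect_equal(rep$max_distance, 0.7, tolerance = 1e-12)

  satisfied <- distance_restraint(data.frame(resno = 1, atom = "HA"),
                                  data.frame(resno = 2, atom = "HA"), 0, 4.0)
  expect_equal(violation_report(ens, list(satisfied))$max_distance, 0)
  # an unbounded restraint can never be violated from above
  loose <- distance_restraint(data.frame(resno = 1, atom = "HA"),
                              data.frame(resno = 2, atom = "HA"), 0, Inf)
  expect_equal(violation_report(ens, list(loose))$max_distance, 0)
  # lower-bound violation
  tight <- distance_restraint(data.frame(resno = 1, atom = "HA"),
                              data.frame(resno = 2, atom = "HA"), 4.2, Inf)
  expect_equal(violation_report(ens, list(tight))$max_distance, 0.5,
               tolerance = 1e-12)
  # unresolvable restraints are reported, not fatal
  ghost <- distance_restraint(data.frame(resno = 9, atom = "HA"),
                              data.frame(resno = 2, atom = "HA"), 0, 3)
  rep <- violation_report(ens, list(stretched, ghost))
  expect_length(rep$unresolved, 1)
  expect_equal(rep$max_distance, 0.7, tolerance = 1e-12)
})

test_that("dihedral violations wrap angles into (-180, 180] before comparison", {
  set.seed(44)
  xyz <- matrix(rnorm(12, sd = 2), 4, 3)
  atoms <- data.frame(chain = "A", resno = 1:4, resname = "ALA",
                      atom = c("C", "N", "CA", "C"))
  ens <- structure_ensemble(atoms, list(xyz))
  th0 <- oracle_dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  sel <- data.frame(resno = 1:4, atom = c("C", "N", "CA", "C"))
  # target placed 340 degrees away, which wraps to a 20-degree deviation
  r <- dihedral_restraint(sel, target = th0 - 340, range = 5)
  rep <- violation_report(ens, dihedral_restraints = list(r))
  expect_equal(rep$max_dihedral, 15, tolerance = 1e-6)
  r2 <- dihedral_restraint(sel, target = th0 - 340, range = 25)
  expect_equal(violation_report(ens, dihedral_restraints =
                                  list(r2))$max_dihedral, 0)
})

test_that("generated ensembles satisfy their own restraints except planted violations", {
  spec <- scenario_spec(seed = 13, n_residues = 10, coord_jitter = 0.25,
                        n_models = 6)
  g <- gen_ensemble(spec, "helix", n_res = 14, max_restraints = 80,
                    n_violated = 3, violation_size = 0.7)
  rep <- violation_report(g$ensemble, g$distance_restraints,
                          g$dihedral_restraints)
  expect_equal(rep$max_distance, 0.7, tolerance = 1e-9)
  expect_equal(rep$max_dihedral, 0)
  expect_length(rep$unresolved, 0)
  # class counts equal the generator bookkeeping
  cl <- classify_distance_restraints(g$distance_restraints)
  expect_equal(unname(cl$counts[c("intraresidue", "sequential", "medium",
                                  "long")]),
               unname(vapply(c("intraresidue", "sequential", "medium",
                               "long"),
                             function(k) sum(g$bookkeeping$class == k),
                             integer(1))))
  # per-restraint violation rows: exactly the planted ones exceed zero
  viol_rows <- which(apply(rep$distance, 1, max) > 1e-9)
  expect_setequal(viol_rows, g$bookkeeping$index[g$bookkeeping$violated])
})
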