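entry_file <- function(...) {
  f <- tempfile(fileext = ".pdb")
  synth_pdb_entry(f, ...)
  f
}

test_that("anchored selection uses closed-boundary expand semantics", {
  f <- entry_file(seed = 1)
  m <- read_structure(f)
  a <- m$atoms[1, ]
  at_pos <- anchor_point("x", c(a$x, a$y, a$z), 2)
  expect_true(1 %in% select_within(m, at_pos))
  # an atom exactly at the boundary is included, epsilon beyond is not
  # (axis-aligned offset so the distance is exact in floating point)
  boundary <- anchor_point("x", c(a$x - 2, a$y, a$z), 2)
  expect_true(1 %in% select_within(m, boundary))
  expect_false(1 %in% select_within(m, anchor_point("x", c(a$x - 2 - 1e-6,
                                                           a$y, a$z), 2)))
})

test_that("by-chain closure returns whole chains straddling the boundary", {
  # RNA chain runs outward from 15 A; within the 22 A radius only part of it
  # lies inside, but the closure must return the entire chain
  f <- entry_file(seed = 2, rna_dist = 15, rna_len = 8)
  m <- read_structure(f)
  anchors <- polymerase_anchors()
  sel <- select_within(m, anchors$base_pair, by_chain = TRUE)
  rna_rows <- which(m$atoms$chain == "R")
  inside <- select_within(m, anchors$base_pair)
  expect_true(length(intersect(rna_rows, inside)) < length(rna_rows))
  expect_true(all(rna_rows %in% sel))
})

test_that("catalytic aspartates are located at the frame anchors", {
  anchors <- polymerase_anchors()
  f <- entry_file(seed = 3)   # Asp Calpha exactly at both anchors
  m <- read_structure(f)
  asp <- locate_catalytic_aspartates(m)
  expect_equal(asp$motif_a$position, anchors$asp_a$position)
  expect_equal(asp$motif_c$position, anchors$asp_c$position)

  # asparagine decoys at the anchors do not qualify
  f2 <- entry_file(seed = 4, asp_resname = "ASN")
  expect_error(locate_catalytic_aspartates(read_structure(f2)),
               class = "no_active_site")

  # the nearest of several candidate aspartates wins
  f3 <- entry_file(seed = 5,
                   asp_a_pos = anchors$asp_a$position + c(1, 0, 0))
  m3 <- read_structure(f3)
  extra <- m3$atoms[m3$atoms$resseq == 10, ][1, ]
  extra$resseq <- 99L
  extra$x <- anchors$asp_a$position[1] + 2
  extra$y <- anchors$asp_a$position[2]
  extra$z <- anchors$asp_a$position[3]
  m3$atoms <- rbind(m3$atoms, extra)
  found <- locate_catalytic_aspartates(m3)
  expect_equal(found$motif_a$distance, 1)
  expect_false(found$motif_a$resseq == 99)
})

test_that("DD distance equals the aspartate separation and is frame-locked", {
  f <- entry_file(seed = 6)
  m <- read_structure(f)
  anchors <- polymerase_anchors()
  # independent oracle: plain Euclidean distance between the two anchors
  expect_equal(dd_distance(m),
               sqrt(sum((anchors$asp_a$position - anchors$asp_c$position)^2)),
               tolerance = 1e-9)
  expect_equal(round(dd_distance(m), 2), 6.93)

  # a planted DD of 7.2 A is returned to within 0.01
  dir7 <- (anchors$asp_c$position - anchors$asp_a$position)
  dir7 <- dir7 / sqrt(sum(dir7^2))
  f72 <- entry_file(seed = 7,
                    asp_c_pos = anchors$asp_a$position + 7.2 * dir7)
  expect_equal(dd_distance(read_structure(f72)), 7.2, tolerance = 0.01)

  # invariance when model AND anchors move together; failure when only the
  # model moves (frame dependence is intended)
  tr <- rigid_transform(rotation_about_axis(c(2, 1, 1), 40), c(5, 5, 5))
  moved <- apply_transform(m, tr)
  moved_anchors <- lapply(anchors, function(a)
    anchor_point(a$label, as.vector(transform_points(a$position, tr)), a$radius))
  expect_equal(dd_distance(moved, moved_anchors), dd_distance(m),
               tolerance = 1e-9)
  expect_error(dd_distance(apply_transform(m, rigid_transform(diag(3),
                                                              c(5, 5, 5)))),
               class = "no_active_site")
})

test_that("DD surveys record, skip and bin per file", {
  anchors <- polymerase_anchors()
  dirv <- (anchors$asp_c$position - anchors$asp_a$position)
  dirv <- dirv / sqrt(sum(dirv^2))
  paths <- character(0)
  for (k in 1:5) paths <- c(paths, entry_file(
    seed = 10 + k, asp_c_pos = anchors$asp_a$position + 5.5 * dirv))
  for (k in 1:5) paths <- c(paths, entry_file(
    seed = 20 + k, asp_c_pos = anchors$asp_a$position + 7.8 * dirv))
  noasp <- entry_file(seed = 30, asp_resname = "ASN")
  sv <- survey_dd(c(paths, noasp))
  expect_equal(nrow(sv$records), 10)
  expect_equal(nrow(sv$skipped), 1)
  expect_equal(nrow(sv$records) + nrow(sv$skipped), 11)  # count conservation
  expect_equal(sv$histogram$count[abs(sv$histogram$mid - 5.55) < 1e-9], 5)
  expect_equal(sv$histogram$count[abs(sv$histogram$mid - 7.85) < 1e-9], 5)
  expect_equal(sum(sv$histogram$count), 10)

  empty <- survey_dd(character(0))
  expect_equal(nrow(empty$records), 0)
})

test_that("monomer trimming keeps only chains near the base-pair anchor", {
  f <- entry_file(seed = 40, rna_dist = 15, rna_len = 3,
                  second_chain_dist = 60)
  m <- read_structure(f)
  trimmed <- trim_to_monomer(m)
  expect_setequal(unique(trimmed$atoms$chain), c("A", "R"))
  # with a 5 A radius the RNA at 15 A goes too
  trimmed5 <- trim_to_monomer(m, radius = 5)
  expect_setequal(unique(trimmed5$atoms$chain), "A")
  expect_error(trim_to_monomer(pdb_structure(polsuper:::empty_atoms())),
               "empty model")
  far <- apply_transform(m, rigid_transform(diag(3), c(500, 0, 0)))
  expect_error(trim_to_monomer(far), "no monomer")
})

test_that("ion pooling conserves counts, positions and duplicates", {
  f1 <- entry_file(seed = 50, ions = c("meA", "meB"))
  f2 <- entry_file(seed = 51)
  f3 <- entry_file(seed = 52, ions = c("meBp"))
  out <- tempfile(); dir.create(out)
  pool <- pool_ions(c(f1, f2, f3), "test", out_dir = out)
  expect_equal(nrow(pool$records), 3)
  expect_identical(basename(pool$file), "IONS-test.pdb")

  back <- read_structure(pool$file)
  expect_equal(nrow(back$atoms), 3)
  expect_lt(max(abs(back$atoms$x - pool$records$x)), 1e-3)
  expect_identical(back$atoms$tag, basename(c(f1, f1, f3)))

  # a file listed twice contributes its ions twice (no dedup)
  pool2 <- pool_ions(c(f1, f1), "dupl", out_dir = out)
  expect_equal(nrow(pool2$records), 4)

  expect_warning(pool_ions(c(f1, tempfile()), "miss", out_dir = out),
                 "skipping unreadable")
})

test_that("ions are assigned to the nearest site within the cutoff", {
  sites <- default_ion_sites()
  at_centroid <- data.frame(element = "MG",
                            x = sites$centroids["meA", 1],
                            y = sites$centroids["meA", 2],
                            z = sites$centroids["meA", 3],
                            source_file = "a", source_chain = "M", resseq = 1)
  res <- assign_ion_sites(at_centroid, sites)
  expect_identical(res$ions$site, "meA")

  # equidistant beyond the cutoff -> OTHER
  midpoint <- (sites$centroids["meB", ] + sites$centroids["meBp", ]) / 2
  faraway <- at_centroid
  faraway[c("x", "y", "z")] <- as.list(midpoint + c(0, 20, 0))
  expect_identical(assign_ion_sites(faraway, sites)$ions$site, "OTHER")

  # three tight Gaussians at the centroids are nearly perfectly recovered,
  # and the labels do not depend on input order
  set.seed(61)
  truth <- rep(rownames(sites$centroids), each = 50)
  cloud <- do.call(rbind, lapply(truth, function(s)
    sites$centroids[s, ] + rnorm(3, sd = 0.5)))
  ions <- data.frame(element = "MG", x = cloud[, 1], y = cloud[, 2],
                     z = cloud[, 3], source_file = "f", source_chain = "M",
                     resseq = seq_along(truth))
  got <- assign_ion_sites(ions, sites)
  expect_gte(mean(got$ions$site == truth), 0.95)
  perm <- sample(nrow(ions))
  got2 <- assign_ion_sites(ions[perm, ], sites)
  expect_identical(got2$ions$site, got$ions$site[perm])

  # per-class breakdown has one column per class
  cls <- rep(c("RdRP", "DdDP"), length.out = nrow(ions))
  withcls <- assign_ion_sites(ions, sites, classes = cls)
  expect_identical(colnames(withcls$class_counts), c("DdDP", "RdRP"))
})
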