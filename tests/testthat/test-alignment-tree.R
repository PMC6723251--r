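mini_tree_yaml <- function(sets) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(sets = sets), f)
  f
}

stub_member <- function(pdb) list(pdb = pdb, chain = "A",
                                  file = paste0(pdb, ".pdb"))

test_that("tree configs validate topology, seeds and cycles", {
  s <- function(name, parent, seed, members)
    list(name = name, parent = parent,
         seed = list(pdb = seed, chain = "A"),
         alignment = "AUTO", region = "FULL",
         members = lapply(members, stub_member))
  good <- mini_tree_yaml(list(
    s("ro01", "ROOT", "a001", c("a001", "a002")),
    s("mi01", "ro01", "a002", c("a002", "a003")),
    s("le01", "mi01", "a003", c("a003", "a004"))))
  tree <- load_tree(good)
  expect_identical(tree$order, c("ro01", "mi01", "le01"))

  expect_error(load_tree(mini_tree_yaml(list(
    s("ro01", "ROOT", "a001", c("a001")),
    s("aa01", "bb01", "a001", c("a001")),
    s("bb01", "aa01", "a001", c("a001"))))), "cycle")

  expect_error(load_tree(mini_tree_yaml(list(
    s("ro01", "ROOT", "a001", c("a001")),
    s("ro01", "ro01", "a001", c("a001"))))), "duplicate set name")

  expect_error(load_tree(mini_tree_yaml(list(
    s("ro01", "ROOT", "zzzz", c("a001"))))), "not among its members")

  expect_error(load_tree(mini_tree_yaml(list(
    s("ro01", "ROOT", "a001", c("a001")),
    s("ch01", "ro01", "a009", c("a009", "a002"))))),
    "not found among parent")
})

test_that("pivot-style sets may hand a different member to their children", {
  # the synthetic tree seeds every child with a NON-seed member of its parent
  fx <- std_tree()
  tree <- load_tree(fx$config)
  root <- tree$sets[[tree$order[1]]]
  child <- tree$sets[[tree$order[2]]]
  expect_identical(child$parent, root$name)
  expect_false(identical(child$seed$pdb, root$seed$pdb))
  hit <- root$members$pdb == child$seed$pdb
  expect_true(any(hit))   # but it is a member of the parent
})

test_that("anchoring premultiplies transforms without changing geometry", {
  fam <- synth_family(family_spec(length = 40, n_members = 4, sigma = 0.1,
                                  seed = 17))
  sup <- ml_superpose(fam$correspondence, fam$traces)
  p <- sup$present[, 1]
  ml_seed <- fitted(sup)[[1]][p, ]

  # parent frame equal to the ML frame: G is the identity
  same <- anchor_to_parent(sup, 1, ml_seed)
  G <- attr(same, "anchor")
  expect_lt(max(abs(G$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(G$translation)), 1e-8)

  # parent frame rotated by a known transform: G recovers it and pairwise
  # member geometry is untouched
  rot <- rigid_transform(rotation_about_axis(c(0, 1, 2), 25), c(3, 3, -1))
  moved <- anchor_to_parent(sup, 1, transform_points(ml_seed, rot))
  G2 <- attr(moved, "anchor")
  expect_lt(max(abs(G2$rotation - rot$rotation)), 1e-9)
  before <- fitted(sup)
  after <- lapply(seq_len(4), function(i)
    transform_points(sup$input_coords[[i]], moved[[i]]))
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(abs(rmsd(before[[i]], before[[j]]) -
                    rmsd(after[[i]], after[[j]])), 1e-9)

  expect_error(anchor_to_parent(sup, 1, ml_seed[1:10, ]), "cover the seed")
})

test_that("run_set writes one output per polymerase chain plus set files", {
  dir <- tempfile(); dir.create(file.path(dir, "in"), recursive = TRUE)
  # four entries; e004 has two polymerase chains (A and B traces of a family)
  fam <- synth_family(family_spec(length = 40, n_members = 5, sigma = 0.05,
                                  seed = 19))
  paths <- character(4)
  for (k in 1:3) {
    paths[k] <- file.path(dir, "in", sprintf("e%03d.pdb", k))
    write_structure(polsuper:::trace_to_structure(
      ca_trace(sprintf("e%03d", k), "A", fam$traces[[k]]$resseq, " ",
               fam$traces[[k]]$resname, fam$traces[[k]]$xyz),
      title = sprintf("SYNTHETIC ENTRY %d", k)), paths[k])
  }
  two <- polsuper:::trace_to_structure(
    ca_trace("e004", "A", fam$traces[[4]]$resseq, " ",
             fam$traces[[4]]$resname, fam$traces[[4]]$xyz),
    title = "SYNTHETIC ENTRY WITH TWO POLYMERASE CHAINS")
  second <- polsuper:::trace_to_structure(
    ca_trace("e004", "B", fam$traces[[5]]$resseq, " ",
             fam$traces[[5]]$resname, fam$traces[[5]]$xyz))
  two$atoms <- rbind(two$atoms, second$atoms)
  paths[4] <- file.path(dir, "in", "e004.pdb")
  write_structure(two, paths[4])

  cfg <- polsuper:::parse_set_config(list(
    name = "test", parent = "ROOT",
    seed = list(pdb = "e001", chain = "A"),
    alignment = "AUTO", region = "FULL",
    members = list(
      list(pdb = "e001", chain = "A", file = paths[1]),
      list(pdb = "e002", chain = "A", file = paths[2]),
      list(pdb = "e003", chain = "A", file = paths[3]),
      list(pdb = "e004", chain = "A", file = paths[4]),
      list(pdb = "e004", chain = "B", file = paths[4]))))
  out <- file.path(dir, "out")
  res <- run_set(cfg, out_dir = out)
  written <- list.files(file.path(out, "test", "pdb"))
  expect_length(written, 5)      # five polymerase chains -> five outputs
  expect_true("e004_B-test.pdb" %in% written)
  # each e004 output contains the complete two-chain entry
  m <- read_structure(file.path(out, "test", "pdb", "e004_B-test.pdb"))
  expect_setequal(unique(m$atoms$chain), c("A", "B"))
  # set files exist
  expect_true(file.exists(file.path(out, "test", "super", "theseus_ave.pdb")))
  expect_true(file.exists(file.path(out, "test", "super",
                                    "theseus_variances.txt")))
  readme <- readLines(file.path(out, "test", "_readme.txt"))
  expect_length(grep("atoms used", readme), 5)
  expect_true(any(grepl("SYNTHETIC ENTRY 2", readme)))
})

test_that("a set of exact copies of the seed stays in the seed frame", {
  dir <- tempfile(); dir.create(file.path(dir, "in"), recursive = TRUE)
  fam <- synth_family(family_spec(length = 30, n_members = 1, sigma = 0, seed = 2))
  tr <- fam$traces[[1]]
  members <- list()
  for (k in 1:3) {
    p <- file.path(dir, "in", sprintf("c%03d.pdb", k))
    write_structure(polsuper:::trace_to_structure(
      ca_trace(sprintf("c%03d", k), "A", tr$resseq, " ", tr$resname, tr$xyz)), p)
    members[[k]] <- list(pdb = sprintf("c%03d", k), chain = "A", file = p)
  }
  cfg <- polsuper:::parse_set_config(list(
    name = "copy", parent = "ROOT", seed = list(pdb = "c001", chain = "A"),
    alignment = "AUTO", region = "FULL", members = members))
  res <- run_set(cfg, out_dir = file.path(dir, "out"))
  # the seed's file coordinates (3-decimal format) are the inherited frame
  seed_file <- extract_ca_trace(read_structure(members[[1]]$file), "A")
  for (id in names(res$aligned_traces))
    expect_lt(rmsd(res$aligned_traces[[id]]$xyz, seed_file$xyz), 1e-6)
})

test_that("unreadable members are skipped with a warning unless strict", {
  fx <- std_tree()
  tree <- load_tree(fx$config)
  cfg <- tree$sets[[tree$order[1]]]
  cfg$members <- rbind(cfg$members,
                       data.frame(pdb = "gone", chain = "A",
                                  file = file.path(fx$dir, "input", "gone.pdb"),
                                  representative = NA_character_))
  out <- tempfile()
  expect_warning(res <- run_set(cfg, out_dir = out), "skipping member gone_A")
  expect_equal(res$skipped$member, "gone_A")
  expect_true(any(grepl("SKIPPED", readLines(file.path(res$set_dir,
                                                       "_readme.txt")))))
  expect_error(run_set(cfg, out_dir = tempfile(), strict = TRUE),
               "gone_A failed")

  # an unreadable seed is always fatal
  cfg2 <- tree$sets[[tree$order[1]]]
  cfg2$members$file[1] <- file.path(fx$dir, "input", "gone.pdb")
  expect_error(run_set(cfg2, out_dir = tempfile()), "seed member unreadable")
})

test_that("tree execution inherits frames exactly and recovers ground truth", {
  fx <- std_tree()
  res <- std_tree_run()
  expect_length(res, 2)
  for (r in res) expect_lt(r$seed_rmsd, 1e-6)

  # every member lands within 3x the planted noise of its true common-frame
  # coordinates over the clean columns
  clean <- which(fx$sigma <= max(fx$sigma[1]) + 1e-12)
  bound <- 3 * sqrt(3) * fx$sigma[1]
  for (r in res) {
    for (id in names(r$aligned_traces)) {
      err <- rmsd(r$aligned_traces[[id]]$xyz[clean, ], fx$truth[[id]][clean, ])
      expect_lt(err, bound)
    }
  }

  # frame-composition consistency: outputs equal anchored-transform-applied
  # originals to numerical precision
  tree <- load_tree(fx$config)
  for (nm in names(res)) {
    r <- res[[nm]]
    s <- tree$sets[[nm]]
    for (i in seq_len(nrow(s$members))) {
      id <- paste(s$members$pdb[i], s$members$chain[i], sep = "_")
      orig <- extract_ca_trace(read_structure(s$members$file[i],
                                              pdb_id = s$members$pdb[i]), "A")
      expect_lt(max(abs(transform_points(orig$xyz, r$transforms[[id]]) -
                          r$aligned_traces[[id]]$xyz)), 1e-8)
    }
  }

  # _All_PDBs mirrors every pdb/ output
  all_dir <- file.path(dirname(res[[1]]$set_dir), "_All_PDBs")
  expect_true(dir.exists(all_dir))
  per_set <- unlist(lapply(res, function(r) list.files(r$pdb_dir)))
  expect_setequal(list.files(all_dir), unique(per_set))
})

test_that("sibling branches remain compatible across the tree", {
  # two children under one root: members of different leaves still superpose
  # over the root core region within a few times the planted noise
  dir <- tempfile()
  fx <- synth_tree(dir, levels = 2, members_per_set = 3, seed = 31)
  tree <- load_tree(fx$config)
  # graft a second child onto the root, seeded by the root's third member
  root <- tree$sets[[tree$order[1]]]
  sib <- root
  sib$name <- "sib1"
  sib$parent <- root$name
  sib$seed <- list(pdb = root$members$pdb[3], chain = "A", frame = NULL)
  sib$members <- root$members[c(3, 1), ]
  sib$region <- tree$sets[[tree$order[2]]]$region
  tree$sets[["sib1"]] <- sib
  tree$order <- c(tree$order, "sib1")
  res <- run_tree(tree, out_dir = tempfile())
  core <- 1:13
  a <- res[[tree$order[2]]]$aligned_traces[[1]]$xyz[core, ]
  b <- res[["sib1"]]$aligned_traces[[1]]$xyz[core, ]
  expect_lt(rmsd(a, b), 3 * sqrt(3) * max(fx$sigma[core]) * 2)
})

test_that("rerunning a tree produces byte-identical outputs", {
  fx <- std_tree()
  tree <- load_tree(fx$config)
  out1 <- tempfile(); out2 <- tempfile()
  run_tree(tree, out_dir = out1)
  run_tree(tree, out_dir = out2)
  f1 <- list.files(out1, recursive = TRUE)
  f2 <- list.files(out2, recursive = TRUE)
  expect_setequal(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("the bundled polymerase catalog encodes the published tree shape", {
  cfg <- system.file("extdata", "polymerase_tree.yaml", package = "polsuper")
  tree <- load_tree(cfg)
  expect_identical(tree$order[1], "pols")
  expect_equal(region_size(tree$sets$pols$region), 13)
  expect_equal(region_size(tree$sets$rdrp$region), 40)
  expect_equal(region_size(tree$sets$psrn$region), 65)
  expect_equal(nrow(tree$sets$opcl$members), 8)
  expect_identical(tree$sets$opcl$seed$pdb, "5f8j")
  expect_identical(tree$sets$psrn$seed$pdb, "5f8g")
  expect_identical(tree$sets$psrn$parent, "opcl")
  # 5d98 contributes two members to fluv, one per polymerase chain
  expect_equal(sum(tree$sets$fluv$members$pdb == "5d98"), 2)
})
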