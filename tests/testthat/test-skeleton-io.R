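pdb_atom_line <- function(serial, resname, chain, resseq, x, y, z, occ) {
  sprintf("ATOM  %5d  C   %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, resname, chain, resseq, x, y, z, occ, 0)
}

test_that("a single chain of collinear nodes reads as one trace with the right length", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK 200 DATASET_ID X1A",
               pdb_atom_line(1, "NEU", "A", 1, 0, 0, 0, 0.3),
               pdb_atom_line(2, "NEU", "A", 2, 1, 0, 0, 0.3),
               pdb_atom_line(3, "NEU", "A", 3, 2, 0, 0, 0.3),
               "TER", "END"), f)
  m <- read_pdb_skeleton(f)
  expect_equal(m$dataset_id, "X1A")
  expect_length(m$traces, 1)
  expect_equal(nrow(m$traces[[1]]$xyz), 3)
  expect_equal(total_trace_length(m), 2)
})

test_that("chain grouping and node order are preserved", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sapply(1:5, function(i) pdb_atom_line(i, "NEU", "A", i, i * 1.5, 0, 0, 0.25)),
    "TER",
    sapply(1:4, function(i) pdb_atom_line(5 + i, "NEU", "B", i, 0, i * 2, 1, 0.25)),
    "TER", "END"), f)
  m <- read_pdb_skeleton(f)
  expect_length(m$traces, 2)
  expect_equal(vapply(m$traces, function(t) nrow(t$xyz), 0L), c(5L, 4L))
  expect_equal(m$traces[[1]]$xyz[, 1], (1:5) * 1.5)
  expect_equal(m$traces[[2]]$xyz[, 2], (1:4) * 2)
})

test_that("write/read round-trip preserves partition, coordinates and radii", {
  set.seed(42)
  m <- random_wlc_model(42, n_traces = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_skeleton(m, f)
  m2 <- read_pdb_skeleton(f)
  expect_length(m2$traces, length(m$traces))
  for (i in seq_along(m$traces)) {
    expect_lte(max(abs(m2$traces[[i]]$xyz - m$traces[[i]]$xyz)), 5e-4)
    expect_lte(max(abs(m2$traces[[i]]$radius - m$traces[[i]]$radius)), 5e-3)
    expect_equal(m2$traces[[i]]$kind, m$traces[[i]]$kind)
  }
  # coordinate fields are byte-stable once quantized to column precision
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_skeleton(m2, f2)
  expect_identical(readLines(f2)[-1], readLines(f)[-1])
})

test_that("a 1000-node random model round-trips within column precision", {
  set.seed(7)
  xyz <- matrix(stats::runif(3000, -50, 50), ncol = 3)
  # enforce non-coincident consecutive nodes
  xyz <- xyz[c(TRUE, rowSums(abs(diff(xyz))) > 1e-6), ]
  m <- skeleton_model(list(neurite_trace(xyz, radius = 0.5, trace_id = "T1")),
                      dataset_id = "RT")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_skeleton(m, f)
  m2 <- read_pdb_skeleton(f)
  expect_lte(max(abs(m2$traces[[1]]$xyz - m$traces[[1]]$xyz)), 0.001)
})

test_that("radius round-trips at occupancy precision and the empty model is valid", {
  m <- skeleton_model(list(neurite_trace(cbind(0:3, 0, 0), radius = 1.23,
                                         trace_id = "T1")), dataset_id = "R")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_skeleton(m, f)
  expect_equal(read_pdb_skeleton(f)$traces[[1]]$radius, rep(1.23, 4))

  empty <- skeleton_model(list(), dataset_id = "EMPTY")
  write_pdb_skeleton(empty, f)
  expect_length(read_pdb_skeleton(f)$traces, 0)
})

test_that("unrepresentable values and malformed input raise errors", {
  tr <- neurite_trace(cbind(0:3, 0, 0), radius = 0.001, trace_id = "T1")
  m <- skeleton_model(list(tr), dataset_id = "BAD")
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_pdb_skeleton(m, f), "rounds to zero")

  tr2 <- neurite_trace(cbind(c(0, 20000), 0, 0), radius = 0.3, trace_id = "T1")
  expect_error(write_pdb_skeleton(skeleton_model(list(tr2), "BAD2"), f),
               "fixed-column range")

  writeLines(c(pdb_atom_line(1, "NEU", "A", 1, 0, 0, 0, 0.3),
               "ATOM  garbage"), f)
  expect_error(read_pdb_skeleton(f), "line 2")

  # a chain with a single node is not analyzable
  writeLines(c(pdb_atom_line(1, "NEU", "A", 1, 0, 0, 0, 0.3), "TER"), f)
  expect_error(read_pdb_skeleton(f), "fewer than 2 nodes")

  # duplicate serials across chains
  writeLines(c(pdb_atom_line(1, "NEU", "A", 1, 0, 0, 0, 0.3),
               pdb_atom_line(2, "NEU", "A", 2, 1, 0, 0, 0.3),
               "TER",
               pdb_atom_line(1, "NEU", "B", 1, 0, 1, 0, 0.3),
               pdb_atom_line(2, "NEU", "B", 2, 1, 1, 0, 0.3)), f)
  expect_error(read_pdb_skeleton(f), "duplicate node_id")
})

test_that("the bfactor radius dialect option remaps the radius column", {
  f <- withr::local_tempfile(fileext = ".pdb")
  line <- sprintf("ATOM  %5d  C   NEU A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  1:2, 1:2, c(0, 1), 0, 0, 0.3, 0.9)
  writeLines(c(line, "TER"), f)
  m <- read_pdb_skeleton(f, dialect_options = list(radius_column = "bfactor"))
  expect_equal(m$traces[[1]]$radius, c(0.9, 0.9))
})

test_that("validate_model reports each violation with identifiers", {
  ok <- random_wlc_model(3, n_traces = 2)
  expect_length(validate_model(ok), 0)

  coin <- skeleton_model(list(neurite_trace(
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    radius = 0.3, trace_id = "TC", validate = FALSE)), "V", validate = FALSE)
  v <- validate_model(coin)
  expect_length(v, 1)
  expect_match(v, "coincident")

  zr <- skeleton_model(list(neurite_trace(
    cbind(0:2, 0, 0), radius = c(0.3, 0, 0.3), trace_id = "TZ",
    validate = FALSE)), "V", validate = FALSE)
  expect_match(validate_model(zr), "nonpositive radius")
})

test_that("total trace length counts neurites only and is rigid-motion invariant", {
  m <- random_wlc_model(11, n_traces = 3)
  soma <- neurite_trace(cbind(c(0, 1, 2), 50, 50), radius = 4, kind = "soma",
                        trace_id = "SOMA", node_id = 9000:9002)
  m2 <- skeleton_model(c(m$traces, list(soma)), dataset_id = "MIX")
  expect_equal(total_trace_length(m2), total_trace_length(m))

  set.seed(5)
  Q <- random_rotation(); shift <- c(3, -7, 11)
  rot <- m
  rot$traces <- lapply(rot$traces, function(tr) {
    tr$xyz <- t(Q %*% t(tr$xyz)) + rep(shift, each = nrow(tr$xyz)); tr
  })
  expect_equal(total_trace_length(rot), total_trace_length(m),
               tolerance = 1e-9)
})
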