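# Lattice estimation, hole detection, per-hole measurement, selection,
# grouping, Navigator export, quality correlation.

test_that("estimate_lattice recovers spacing and rotation of synthetic lattices", {
  sim <- simulate_pair(tiny_scene(noise = TRUE, seed = 21))
  lat <- estimate_lattice(sim$pair$unfiltered)
  expect_equal(sqrt(sum(lat$v1_px^2)), 24, tolerance = 0.5)
  expect_equal(sqrt(sum(lat$v2_px^2)), 24, tolerance = 0.5)

  sim15 <- simulate_pair(tiny_scene(noise = TRUE, angle = 15, seed = 22))
  lat15 <- estimate_lattice(sim15$pair$unfiltered,
                            spacing_hint_um = 24 * 144.6e-4)
  expect_equal(sqrt(sum(lat15$v1_px^2)), 24, tolerance = 0.5)
  ang <- atan2(lat15$v1_px[2], lat15$v1_px[1]) * 180 / pi
  # basis vectors are recovered up to lattice symmetry: angle mod 90
  ang_mod <- ((ang - 15) %% 90)
  expect_lt(min(ang_mod, 90 - ang_mod), 1)
  expect_error(estimate_lattice(make_plane(matrix(5, 64, 64))),
               class = "lattice_detection")
  set.seed(1)
  expect_error(
    estimate_lattice(make_plane(matrix(rnorm(64^2, 100, 0.01), 64, 64))),
    class = "lattice_detection")
})

test_that("detect_holes finds every interior hole with sub-pixel centres", {
  sim <- simulate_pair(tiny_scene(noise = FALSE))
  lat <- estimate_lattice(sim$pair$unfiltered)
  holes <- detect_holes(sim$pair$unfiltered, lat)
  truth <- sim$truth[!sim$truth$edge, ]
  expect_equal(nrow(holes), nrow(truth))
  idx <- match_truth(holes, truth)
  expect_equal(sort(idx), seq_len(nrow(truth)))  # one-to-one
  err <- sqrt((holes$row_px - truth$row_px[idx])^2 +
                (holes$col_px - truth$col_px[idx])^2)
  expect_lt(max(err), 1)
})

test_that("border holes are flagged edge and excluded by default", {
  sim <- simulate_pair(tiny_scene(noise = FALSE))
  lat <- sim$lattice
  all_holes <- detect_holes(sim$pair$unfiltered, lat, include_edge = TRUE)
  default_holes <- detect_holes(sim$pair$unfiltered, lat)
  expect_gt(sum(has_edge <- all_holes$flags == "edge"), 0)
  expect_equal(nrow(default_holes), nrow(all_holes) - sum(has_edge))
  expect_false(any(default_holes$flags == "edge"))
})

test_that("a blank image yields no holes even with a valid lattice", {
  lat <- hole_lattice(c(16, 16), c(24, 0), c(0, 24), 6)
  set.seed(2)
  blank <- make_plane(matrix(rnorm(256 * 256, 100, 1), 256, 256))
  holes <- detect_holes(blank, lat)
  expect_equal(nrow(holes), 0L)
})

test_that("measure_holes equals a pixel-loop oracle and matches truth exactly without noise", {
  sim <- simulate_pair(tiny_scene(thickness_field = 30, noise = FALSE))
  pair <- sim$pair
  lat <- sim$lattice
  holes <- detect_holes(pair$unfiltered, lat)
  holes <- measure_holes(holes, pair, PROF_200M)
  expect_true(all(abs(holes$thickness_nm - 30) < 1e-6))
  # brute-force loop oracle over the disk for 5 holes
  radius <- 0.5 * lat$hole_radius_px
  set.seed(4)
  for (k in sample(nrow(holes), 5)) {
    r0 <- round(holes$row_px[k]); c0 <- round(holes$col_px[k])
    vals_i <- c(); vals_z <- c()
    for (dr in -ceiling(radius):ceiling(radius)) {
      for (dc in -ceiling(radius):ceiling(radius)) {
        if (dr^2 + dc^2 <= radius^2) {
          vals_i <- c(vals_i, pair$unfiltered$data[r0 + dr, c0 + dc])
          vals_z <- c(vals_z, pair$filtered$data[r0 + dr, c0 + dc])
        }
      }
    }
    expect_equal(holes$mean_I[k], mean(vals_i), tolerance = 1e-12)
    expect_equal(holes$thickness_nm[k],
                 thickness_filter(mean(vals_i), mean(vals_z), PROF_200M),
                 tolerance = 1e-12)
  }
})

test_that("holes over dead regions are flagged invalid", {
  sim <- simulate_pair(tiny_scene(thickness_field = 30, noise = FALSE))
  pair <- sim$pair
  holes <- detect_holes(pair$unfiltered, sim$lattice)
  # kill the first hole's pixels in both channels
  r0 <- round(holes$row_px[1]); c0 <- round(holes$col_px[1])
  pair$unfiltered$data[(r0 - 6):(r0 + 6), (c0 - 6):(c0 + 6)] <- 0
  pair$filtered$data[(r0 - 6):(r0 + 6), (c0 - 6):(c0 + 6)] <- 0
  measured <- measure_holes(holes, pair, PROF_200M)
  expect_true(has_flag <- grepl("invalid", measured$flags[1]))
  expect_false(is.finite(measured$thickness_nm[1]))
  sel <- select_holes(measured, selection_policy(0, 1000))
  expect_false(sel$selected[1])
})

test_that("selection applies the inclusive 20-40 nm window", {
  df <- data.frame(id = 1:4, lat_i = 0:3, lat_j = 0L,
                   row_px = 1, col_px = 1, score = 1,
                   mean_I = 10, mean_Izl = 9,
                   thickness_nm = c(10, 25, 35, 50),
                   selected = FALSE, group_id = NA_integer_, flags = "",
                   stringsAsFactors = FALSE)
  holes <- icethick:::new_hole_set(df)
  sel <- select_holes(holes, selection_policy())   # default window 20-40
  expect_equal(sel$selected, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(unname(attr(sel, "summary")),
               c(1, 2, 1, 0))
  # boundary values select (closed interval)
  holes$thickness_nm <- c(20, 40, 19.999, 40.001)
  selb <- select_holes(holes, selection_policy(20, 40))
  expect_equal(selb$selected, c(TRUE, TRUE, FALSE, FALSE))
  # default policy bounds
  pol <- selection_policy()
  expect_equal(c(pol$t_min_nm, pol$t_max_nm), c(20, 40))
  # negative raw thickness is clamped before classification
  holes$thickness_nm <- c(-2, 25, 25, 25)
  seln <- select_holes(holes, selection_policy(20, 40))
  expect_equal(unname(attr(seln, "summary"))[1], 1)  # counted as below
})

test_that("reselect_holes is idempotent and needs stored thicknesses", {
  sim <- simulate_pair(tiny_scene(
    thickness_field = make_thickness_field("gradient", c(256, 256),
                                           from = 10, to = 70),
    noise = FALSE))
  holes <- detect_holes(sim$pair$unfiltered, sim$lattice)
  holes <- measure_holes(holes, sim$pair, PROF_200M)
  pol <- selection_policy(20, 40)
  s1 <- select_holes(holes, pol)
  s2 <- reselect_holes(s1, pol)
  expect_equal(s2$selected, s1$selected)
  expect_equal(attr(s2, "summary"), attr(s1, "summary"))
  # widening selects every unflagged hole
  wide <- reselect_holes(s1, selection_policy(0, 1000))
  expect_true(all(wide$selected[!nzchar(wide$flags)]))
  # missing thickness errors and lists the ids
  broken <- s1
  broken$thickness_nm[c(2, 5)] <- NA
  expect_error(reselect_holes(broken, pol), "2, 5",
               class = "missing_thickness")
})

test_that("reselection scales to thousands of stored points", {
  n <- 5000
  df <- data.frame(id = seq_len(n), lat_i = rep(1:70, length.out = n),
                   lat_j = rep(1:72, length.out = n),
                   row_px = 1, col_px = 1, score = 1,
                   mean_I = 10, mean_Izl = 9,
                   thickness_nm = with_seed_test(8, runif(n, 0, 80)),
                   selected = FALSE, group_id = NA_integer_, flags = "",
                   stringsAsFactors = FALSE)
  holes <- icethick:::new_hole_set(df)
  pol <- selection_policy(20, 40)
  res <- reselect_holes(holes, pol)
  expect_equal(res$selected,
               df$thickness_nm >= 20 & df$thickness_nm <= 40)
})

test_that("grouping emits only selected holes and partitions the selection", {
  # one full 3x3 block selected
  df <- expand.grid(lat_i = 0:2, lat_j = 0:2)
  df <- data.frame(id = 1:9, df, row_px = df$lat_i * 10 + 5,
                   col_px = df$lat_j * 10 + 5, score = 1, mean_I = 10,
                   mean_Izl = 9, thickness_nm = 30, selected = TRUE,
                   group_id = NA_integer_, flags = "",
                   stringsAsFactors = FALSE)
  holes <- icethick:::new_hole_set(df)
  g <- group_holes(holes, c(3, 3))
  expect_length(g, 1)
  expect_setequal(g[[1]]$member_ids, 1:9)
  # two members deselected: one partial group, skipped ids absent
  holes2 <- holes
  holes2$selected[c(3, 7)] <- FALSE
  g2 <- group_holes(holes2, c(3, 3))
  expect_length(g2, 1)
  expect_length(g2[[1]]$member_ids, 7)
  expect_false(any(c(3, 7) %in% g2[[1]]$member_ids))
  # nothing selected: empty list
  holes3 <- holes
  holes3$selected <- FALSE
  expect_length(group_holes(holes3, c(3, 3)), 0)
})

test_that("grouping partitions arbitrary selections (randomized property)", {
  for (seed in 1:10) {
    n_side <- 8
    df <- expand.grid(lat_i = seq_len(n_side) - 1,
                      lat_j = seq_len(n_side) - 1)
    n <- nrow(df)
    sel <- with_seed_test(seed, runif(n) < 0.5)
    df <- data.frame(id = seq_len(n), df,
                     row_px = df$lat_i * 12 + 6, col_px = df$lat_j * 12 + 6,
                     score = 1, mean_I = 10, mean_Izl = 9,
                     thickness_nm = 30, selected = sel,
                     group_id = NA_integer_, flags = "",
                     stringsAsFactors = FALSE)
    holes <- icethick:::new_hole_set(df)
    pattern <- list(c(3, 3), c(2, 4), c(1, 1))[[(seed %% 3) + 1]]
    g <- group_holes(holes, pattern)
    members <- unlist(lapply(g, `[[`, "member_ids"))
    expect_equal(sort(members), df$id[sel])       # union == selected set
    expect_false(any(duplicated(members)))        # disjoint
    sizes <- vapply(g, function(x) length(x$member_ids), integer(1))
    expect_true(all(sizes >= 1 & sizes <= prod(pattern)))
    gh <- attr(g, "holes")
    expect_true(all(is.na(gh$group_id[!gh$selected])))
    # anchors are members of their own groups
    for (grp in g) expect_true(grp$anchor_id %in% grp$member_ids)
  }
})

test_that("navigator export/parse round trip is lossless", {
  sim <- simulate_pair(tiny_scene(
    thickness_field = make_thickness_field("gradient", c(256, 256),
                                           from = 10, to = 70),
    noise = FALSE))
  holes <- detect_holes(sim$pair$unfiltered, sim$lattice)
  holes <- measure_holes(holes, sim$pair, PROF_200M)
  holes <- select_holes(holes, selection_policy(20, 40))
  g <- group_holes(holes, c(3, 3))
  holes <- attr(g, "holes")
  path <- withr::local_tempfile(fileext = ".nav")
  # identity transform keeps pixel coordinates in the stage fields
  export_navigator(holes, path, groups = g,
                   transform = stage_transform(matrix_2x2 = diag(2)),
                   policy = selection_policy(20, 40))
  back <- parse_navigator(path)
  expect_equal(nrow(back), nrow(holes))
  expect_equal(back$id, holes$id)
  expect_equal(back$thickness_nm, round(holes$thickness_nm, 1))
  expect_equal(back$selected, holes$selected)
  expect_equal(back$row_px, holes$row_px, tolerance = 1e-8)
  expect_equal(back$col_px, holes$col_px, tolerance = 1e-8)
  expect_equal(back$group_id, holes$group_id)
  # reselection from the parsed file matches reselection in memory
  re_file <- reselect_holes(back, selection_policy(25, 35))
  re_mem <- reselect_holes(holes, selection_policy(25, 35))
  agree <- abs(holes$thickness_nm %% 0.1 - 0.05) > 0.005  # rounding ties
  expect_equal(re_file$selected[agree], re_mem$selected[agree])
})

test_that("navigator formatting follows the documented conventions", {
  df <- data.frame(id = 1L, lat_i = 0L, lat_j = 0L,
                   row_px = 100, col_px = 200, score = 1,
                   mean_I = 10, mean_Izl = 9, thickness_nm = 30.04,
                   selected = TRUE, group_id = NA_integer_, flags = "",
                   stringsAsFactors = FALSE)
  holes <- icethick:::new_hole_set(df)
  lines <- export_navigator(holes,
                            transform = stage_transform(matrix_2x2 = diag(2)))
  expect_true(any(grepl("^AdocVersion", lines)))
  expect_true(any(lines == "Note = 30.0 nm"))
  expect_true(any(lines == "Acquire = 1"))
  expect_true(any(lines == "Color = 0"))
  expect_true(any(lines == "[Item = 1]"))
  # empty hole list: header-only document
  empty <- export_navigator(holes[0, ],
                            transform = stage_transform(matrix_2x2 = diag(2)))
  expect_false(any(grepl("^\\[Item", empty)))
  expect_true(any(grepl("^AdocVersion", empty)))
  # singular transform refused
  expect_error(stage_transform(matrix_2x2 = matrix(0, 2, 2)),
               class = "singular_transform")
  # CRLF input is accepted
  path <- withr::local_tempfile(fileext = ".nav")
  export_navigator(holes, path,
                   transform = stage_transform(matrix_2x2 = diag(2)))
  crlf <- gsub("\n", "\r\n", paste(readLines(path), collapse = "\n"))
  writeBin(charToRaw(paste0(crlf, "\r\n")), path)
  expect_equal(parse_navigator(path)$thickness_nm, 30.0)
})

test_that("correlate_quality reports a positive rank correlation for a monotone table", {
  sim <- simulate_pair(tiny_scene(
    thickness_field = make_thickness_field("gradient", c(256, 256),
                                           from = 10, to = 70),
    noise = FALSE))
  holes <- detect_holes(sim$pair$unfiltered, sim$lattice)
  holes <- measure_holes(holes, sim$pair, PROF_200M)
  # CTF resolution worsens (grows) monotonically with thickness
  qt <- data.frame(id = holes$id,
                   ctf_resolution_a = 2 + 0.05 * holes$thickness_nm)
  qc <- correlate_quality(holes, qt)
  expect_gt(qc$spearman_rho, 0.95)
  expect_true(all(diff(qc$binned$mean_ctf_resolution_a) > 0))
  # permuted quality column: negligible correlation
  qt_perm <- qt
  qt_perm$ctf_resolution_a <- with_seed_test(6,
                                             sample(qt$ctf_resolution_a))
  qc_perm <- correlate_quality(holes, qt_perm)
  expect_lt(abs(qc_perm$spearman_rho), 0.3)
  # no matching ids
  expect_error(correlate_quality(holes,
                                 data.frame(id = -1,
                                            ctf_resolution_a = 3)),
               class = "empty_join")
})

test_that("hole tables round-trip through CSV", {
  sim <- simulate_pair(tiny_scene(noise = FALSE))
  holes <- detect_holes(sim$pair$unfiltered, sim$lattice)
  holes <- measure_holes(holes, sim$pair, PROF_200M)
  holes <- select_holes(holes, selection_policy())
  path <- withr::local_tempfile(fileext = ".csv")
  write_holes_csv(holes, path)
  back <- read_holes_csv(path)
  expect_equal(back$thickness_nm, holes$thickness_nm, tolerance = 1e-9)
  expect_equal(back$selected, holes$selected)
  expect_equal(back$flags, holes$flags)
})
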