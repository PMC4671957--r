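test_that("topology score counts components inside their native spheres", {
  expect_equal(topology_score(fx3$components, fx3$components), 1)

  native <- fx3$components
  pred <- native
  pred[[2]] <- apply_transform(native[[2]],
                               rigid_transform(translation =
                                 c(2 * native[[2]]$rgyr, 0, 0)))
  expect_equal(topology_score(pred, native), 2 / 3)

  # boundary is inclusive: displacement exactly rgyr counts as correct
  # (two-atom construction keeps com and rgyr exactly representable)
  atoms <- data.frame(name = c("CA", "CA"), resno = 1:2, resname = "GLY",
                      element = "C", x = c(-1, 1), y = 0, z = 0)
  nat <- new_component("N", atoms)            # com (0,0,0), rgyr exactly 1
  atoms$x <- atoms$x + 1                      # displaced by exactly rgyr
  prd <- new_component("N", atoms)
  expect_equal(topology_score(list(prd), list(nat)), 1)
  atoms$x <- atoms$x + 1e-9                   # just outside the sphere
  expect_equal(topology_score(list(new_component("N", atoms)), list(nat)), 0)

  expect_error(topology_score(pred[1:2], native), "counts")
})

test_that("component placement score recovers known transforms", {
  cm <- fx3$components[[1]]
  cps0 <- component_placement_score(cm, cm)
  expect_equal(cps0$translation, 0)
  expect_equal(cps0$rotation, 0)

  moved <- apply_transform(cm, rigid_transform(translation = c(3, 4, 0)))
  cps <- component_placement_score(moved, cm)
  expect_equal(cps$translation, 5)
  expect_equal(cps$rotation, 0, tolerance = 1e-6)

  theta <- 90
  q <- c(cos(theta / 2 * pi / 180), 0, 0, sin(theta / 2 * pi / 180))
  rot <- apply_transform(cm, rigid_transform(q))
  cps <- component_placement_score(rot, cm)
  expect_equal(cps$translation, 0, tolerance = 1e-9)
  expect_equal(cps$rotation, 90, tolerance = 1e-6)

  # arbitrary known (t, theta) is returned exactly
  theta2 <- 37.5
  ax <- c(1, 2, -1) / sqrt(6)
  q2 <- c(cos(theta2 / 2 * pi / 180), sin(theta2 / 2 * pi / 180) * ax)
  t2 <- c(-2, 5, 1)
  moved2 <- apply_transform(cm, rigid_transform(q2, t2))
  cps2 <- component_placement_score(moved2, cm)
  expect_equal(cps2$translation, sqrt(sum(t2^2)), tolerance = 1e-6)
  expect_equal(cps2$rotation, theta2, tolerance = 1e-6)

  # rotation angle is symmetric in the direction of comparison
  expect_equal(component_placement_score(cm, moved2)$rotation,
               cps2$rotation, tolerance = 1e-6)

  expect_error(component_placement_score(cm, fx3$components[[2]]), "C-alpha")
})

test_that("assembly placement score averages the component scores", {
  cps <- list(list(translation = 2, rotation = 10),
              list(translation = 4, rotation = 20))
  aps <- assembly_placement_score(cps)
  expect_equal(aps$translation, 3)
  expect_equal(aps$rotation, 15)
  expect_equal(assembly_placement_score(cps[1]), cps[[1]])
  expect_error(assembly_placement_score(list()), "empty")
})

test_that("permutation-aware RMSD resolves identical components", {
  expect_equal(assembly_rmsd(fx3$components, fx3$components)$rmsd, 0)

  # two identical components with swapped labels at native positions
  fxid <- make_assembly(fixture_spec(seed = 9, identical_pairs = list(c(1, 2)),
                                     residues = c(30, 30)))
  native <- fxid$components
  swap_pos <- function(a, b) {
    list(apply_transform(a, rigid_transform(translation = b$com - a$com)),
         apply_transform(b, rigid_transform(translation = a$com - b$com)))
  }
  # place copy 1 where copy 2 sits and vice versa; identical internal coords
  sw <- swap_pos(native[[1]], native[[2]])
  pred <- native
  pred[[1]] <- sw[[1]]; pred[[2]] <- sw[[2]]
  # the two placed copies were built from the same chain, so after the swap
  # each predicted copy reproduces the other native copy only if their
  # internal orientations match; compare against brute force instead
  res <- assembly_rmsd(pred, native)
  groups <- identical_component_groups(native)
  expect_equal(groups[[1]], c(1, 2))
  # brute force over both correspondences of the identical pair
  rms <- function(p, q) {
    sqrt(mean(rowSums((calpha_coords(p) - calpha_coords(q))^2)))
  }
  id_corr <- mean(c(rms(pred[[1]], native[[1]]), rms(pred[[2]], native[[2]]),
                    rms(pred[[3]], native[[3]])))
  sw_corr <- mean(c(rms(pred[[1]], native[[2]]), rms(pred[[2]], native[[1]]),
                    rms(pred[[3]], native[[3]])))
  expect_equal(res$rmsd, min(id_corr, sw_corr))
  expect_lte(res$rmsd, id_corr)                 # minimization can only help
})

test_that("RMSD correspondence matches exhaustive enumeration on 4 identical copies", {
  base <- make_component(12, seed = 5, id = "A")
  offs <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0), c(0, 0, 20))
  native <- lapply(1:4, function(i) {
    cm <- apply_transform(base, rigid_transform(translation = offs[i, ]))
    cm$id <- LETTERS[i]
    cm
  })
  set.seed(17)
  jitter <- matrix(rnorm(12, sd = 2), 4, 3)
  scramble <- c(3, 1, 4, 2)
  pred <- lapply(1:4, function(i) {
    apply_transform(native[[scramble[i]]],
                    rigid_transform(translation = jitter[i, ]))
  })
  res <- assembly_rmsd(pred, native, groups = list(1:4))
  rms <- function(p, q) {
    sqrt(mean(rowSums((calpha_coords(p) - calpha_coords(q))^2)))
  }
  cost <- outer(1:4, 1:4, Vectorize(function(i, j) rms(pred[[i]], native[[j]])))
  perms <- gafem:::all_permutations(4)
  brute <- min(apply(perms, 1, function(p) mean(cost[cbind(1:4, p)])))
  expect_equal(res$rmsd, brute)
  expect_equal(res$correspondence, scramble)
})

test_that("full assessment applies the RMSD correspondence before TS and CPS", {
  a <- assess_assembly(fx3$components, fx3$components)
  expect_equal(a$ts, 1)
  expect_equal(a$aps$translation, 0)
  expect_equal(a$aps$rotation, 0, tolerance = 1e-6)
  expect_equal(a$rmsd, 0)
  expect_equal(a$correspondence, 1:3)
})
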