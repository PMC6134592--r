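fixture_cube <- function() {
  datacube(bind_obs(
    data.frame(metabolite = c("m1", "m2", "m3"), organism = control_name(),
               environment = "E1",
               action = c("detected", "detected", "not_detected")),
    data.frame(metabolite = c("m1", "m2"), organism = "OrgA",
               environment = "E1", action = c("increased", "decreased"),
               log2fc = c(2.5, -1)),
    data.frame(metabolite = "m1", organism = "OrgB", environment = "E1",
               action = "no_change"),
    data.frame(metabolite = "m1", organism = "OrgA", environment = "E2",
               action = "decreased", log2fc = -3)))
}

cell_of <- function(tab, row, col) {
  tab$cells[tab$cells$row == row & tab$cells$column == col, ]
}

test_that("one-environment table puts the control first and fills gaps checkered", {
  tab <- one_environment(fixture_cube(), "E1")
  expect_identical(tab$column_labels, c(control_name(), "OrgA", "OrgB"))
  expect_identical(tab$row_labels, c("m1", "m2", "m3"))
  expect_equal(nrow(tab$cells), 9)
  expect_identical(cell_of(tab, "m1", "OrgA")$action, "increased")
  expect_equal(cell_of(tab, "m1", "OrgA")$shade, 0.5)  # confidence 2.5 / 5
  # unobserved (m2, OrgB) renders checkered
  expect_identical(cell_of(tab, "m2", "OrgB")$color, "checkered")
  # control column colours only ever tan or gray
  ctrl <- tab$cells[tab$cells$column == control_name(), ]
  expect_true(all(ctrl$color %in% c("tan", "gray")))
  expect_error(one_environment(fixture_cube(), "E9"), "unknown environment")
})

test_that("one-organism table spans environments; control selection compares pools", {
  tab <- one_organism(fixture_cube(), "OrgA")
  expect_identical(tab$column_labels, c("E1", "E2"))
  expect_identical(tab$row_labels, c("m1", "m2"))
  # m2 was never assayed in E2 for OrgA: union row set, checkered gap
  expect_identical(cell_of(tab, "m2", "E2")$action, "not_investigated")

  ctrl <- one_organism(fixture_cube(), control_name())
  expect_true(all(ctrl$cells$action %in% c("detected", "not_detected")))
  expect_error(one_organism(fixture_cube(), "nobody"), "unknown organism")
})

test_that("one-metabolite view disambiguates via search", {
  cube <- fixture_cube()
  tab <- one_metabolite(cube, "m2")
  expect_identical(tab$dimension, "metabolite")
  expect_identical(tab$row_labels, "E1")
  # only organisms with observations on the compound become columns
  expect_identical(tab$column_labels, c(control_name(), "OrgA"))
  expect_error(one_metabolite(cube, "zzz"), class = "exocube_empty_result")
  expect_error(one_metabolite(cube, "m"), class = "exocube_ambiguous_match")
  err <- tryCatch(one_metabolite(cube, "m"), error = identity)
  expect_match(conditionMessage(err), "m1, m2, m3")
  # a metabolite registered but observed nowhere yields an empty table
  cube$metabolites <- rbind(cube$metabolites,
                            data.frame(name = "orphan", putative = FALSE,
                                       annotation = NA, msi_level = NA))
  tab <- one_metabolite(cube, "orphan")
  expect_length(tab$row_labels, 0)
  expect_equal(nrow(tab$cells), 0)
})

test_that("any shared cell is identical across the three slice views", {
  for (seed in 1:8) {
    cube <- generate_cube(cube_spec(
      n_metabolites = 12, n_organisms = 3, n_environments = 2, seed = seed))
    env_tab <- one_environment(cube, "Env1")
    for (org in c("Org01", control_name())) {
      org_tab <- one_organism(cube, org)
      for (m in intersect(env_tab$row_labels, org_tab$row_labels)) {
        a <- cell_of(env_tab, m, org)
        b <- cell_of(org_tab, m, "Env1")
        expect_identical(unlist(a[1, c("action", "shade", "color")],
                                use.names = FALSE),
                         unlist(b[1, c("action", "shade", "color")],
                                use.names = FALSE),
                         info = sprintf("seed %d, %s / %s", seed, org, m))
      }
    }
    m1 <- env_tab$row_labels[1]
    met_tab <- one_metabolite(cube, m1)
    for (org in met_tab$column_labels) {
      a <- cell_of(env_tab, m1, org)
      b <- cell_of(met_tab, "Env1", org)
      expect_identical(unlist(a[1, c("action", "shade", "color")],
                              use.names = FALSE),
                       unlist(b[1, c("action", "shade", "color")],
                              use.names = FALSE))
    }
  }
})

test_that("the web draws edges only for increases and decreases", {
  web <- build_web(fixture_cube(), "E1")
  expect_equal(nrow(web$edges), 2)           # OrgA on m1, m2; OrgB draws none
  expect_setequal(web$edges$action, c("increased", "decreased"))
  expect_identical(web$organisms$name, c("OrgA", "OrgB"))
  met <- web$metabolites
  expect_identical(met$name, c("m1", "m2"))  # m3 undetected, no interactions
  expect_identical(met$degree, c(1L, 1L))
  expect_true(all(met$in_control))
})

test_that("products absent from the control appear as hollow nodes", {
  cube <- datacube(bind_obs(
    data.frame(metabolite = "made", organism = control_name(),
               environment = "E", action = "not_detected"),
    data.frame(metabolite = "made", organism = "OrgA", environment = "E",
               action = "increased", log2fc = 1.5)))
  web <- build_web(cube, "E")
  expect_false(web$metabolites$in_control[web$metabolites$name == "made"])
  expect_equal(web$metabolites$degree, 1L)
})

test_that("node degree equals the brute-force count of interacting organisms", {
  for (seed in 1:8) {
    cube <- generate_cube(cube_spec(
      n_metabolites = 15, n_organisms = 5, seed = seed))
    web <- build_web(cube, "Env1")
    obs <- cube$observations
    for (m in web$metabolites$name) {
      brute <- length(unique(obs$organism[
        obs$environment == "Env1" & obs$metabolite == m &
          obs$organism != control_name() &
          obs$action %in% c("increased", "decreased")]))
      expect_equal(web$metabolites$degree[web$metabolites$name == m], brute)
    }
    # web/table consistency: per-organism edge count = directional cells
    env_tab <- one_environment(cube, "Env1")
    for (o in web$organisms$name) {
      cells <- env_tab$cells[env_tab$cells$column == o, ]
      expect_equal(sum(web$edges$organism == o),
                   sum(cells$action %in% c("increased", "decreased")))
    }
  }
})

test_that("graph exports round-trip and keep the colour vocabulary", {
  web <- build_web(worked_example_fixture(), "R2A")
  f <- tempfile(fileext = ".json")
  export_graph(web, f)
  back <- import_graph(f)
  expect_identical(back$metabolites, web$metabolites)
  expect_identical(back$organisms, web$organisms)
  expect_identical(back$edges, web$edges)

  g <- tempfile(fileext = ".graphml")
  export_graph(web, g, format = "graphml")
  ig <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(ig), nrow(web$edges))
  expect_equal(igraph::vcount(ig), nrow(web$metabolites) + nrow(web$organisms))

  # empty graph still exports valid files with empty lists
  quiet <- datacube(data.frame(metabolite = "m", organism = "A",
                               environment = "E", action = "no_change"))
  fe <- tempfile(fileext = ".json")
  export_graph(build_web(quiet, "E"), fe)
  payload <- jsonlite::read_json(fe)
  expect_length(payload$links, 0)

  tab <- one_environment(worked_example_fixture(), "R2A")
  ft <- tempfile(fileext = ".tsv")
  export_table(tab, ft)
  exported <- utils::read.table(ft, sep = "\t", header = TRUE)
  expect_true(all(exported$color %in%
                    c("tan", "gray", "red", "blue", "white", "checkered")))
  expect_equal(nrow(exported), nrow(tab$cells))
})
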