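# small hand-built forests used across test files

toy_forest <- function() {
  lineage_forest(data.frame(
    cell_id = c("a", "a1", "a2"),
    parent_id = c(NA, "a", "a"),
    birth_time = c(0, 2.7, 2.7),
    end_time = c(2.7, 8, 8),
    end_fate = c("divided", "censored", "censored")
  ), movie_end = 8)
}

# one bystander plus a division at t = 5: alive count 2 before, 3 after
rate_fixture_forest <- function() {
  lineage_forest(data.frame(
    cell_id = c("b", "m", "d1", "d2"),
    parent_id = c(NA, NA, "m", "m"),
    birth_time = c(0, 0, 5, 5),
    end_time = c(10, 5, 10, 10),
    end_fate = c("censored", "divided", "censored", "censored")
  ), movie_end = 10)
}

# random forest with exact per-frame areas, for decomposition closure
random_area_forest <- function(seed, n_founders = 3, movie_end = 6,
                               frame_step = 1) {
  set.seed(seed)
  cells <- list()
  counter <- 0
  new_id <- function() {
    counter <<- counter + 1
    sprintf("r%04d", counter)
  }
  spawn <- function(parent, birth) {
    id <- new_id()
    life <- runif(1, 1.2, 2.8)
    end <- birth + life
    if (end >= movie_end) {
      cells[[id]] <<- list(cell_id = id, parent_id = parent,
                           birth_time = birth, end_time = movie_end,
                           end_fate = "censored")
      return(invisible())
    }
    fate <- sample(c("divided", "extruded"), 1, prob = c(0.8, 0.2))
    cells[[id]] <<- list(cell_id = id, parent_id = parent,
                         birth_time = birth, end_time = end, end_fate = fate)
    if (fate == "divided") {
      spawn(id, end)
      spawn(id, end)
    }
  }
  for (i in seq_len(n_founders)) spawn(NA_character_, 0)
  cells <- dplyr::bind_rows(lapply(cells, tibble::as_tibble))
  grid <- seq(0, movie_end, by = frame_step)
  areas <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    tt <- grid[grid >= cells$birth_time[i] & grid < cells$end_time[i]]
    if (cells$end_time[i] >= movie_end) {
      tt <- grid[grid >= cells$birth_time[i] & grid <= movie_end]
    }
    if (length(tt) == 0) return(NULL)
    tibble::tibble(cell_id = cells$cell_id[i], t = tt,
                   area = runif(length(tt), 5, 40))
  })
  lineage_forest(cells, areas = areas, movie_end = movie_end)
}

# small config that runs fast but exercises all phases
fast_config <- function(...) {
  sim_config(n_init = 4, t_end = 30, ...)
}
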