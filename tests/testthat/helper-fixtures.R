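# Shared fixtures, all built in code.

tiny_floor <- function() floor_model(n_modes_x = 2, n_modes_y = 2)

four_sensors <- function()
  rbind(c(0.5, 0.5), c(3.5, 0.5), c(2, 2.5), c(0.5, 4.5))

# small mixed-activity design used by fast end-to-end tests
small_design <- function(seed = 7, counts = c(fall = 20, walk = 10,
                                              bag_drop = 10, ball_drop = 10,
                                              free_jump = 10)) {
  inv <- list(
    list(activity = "fall", count = counts[["fall"]],
         params = list(mass_kg = 70), position = c(2, 2.5)),
    list(activity = "walk", count = counts[["walk"]],
         params = list(mass_kg = 70), path = rbind(c(0.5, 1), c(3.5, 4))),
    list(activity = "bag_drop", count = counts[["bag_drop"]],
         params = list(mass_kg = 10, drop_height_m = 0.6),
         position = c(1, 1.2)),
    list(activity = "ball_drop", count = counts[["ball_drop"]],
         params = list(mass_kg = 0.6, drop_height_m = 1.45),
         position = c(2.8, 3.2)),
    list(activity = "free_jump", count = counts[["free_jump"]],
         params = list(mass_kg = 70), position = c(1.2, 3.8)))
  scenario_design(inv, four_sensors(), fs = 400, duration = 2, seed = seed)
}

small_dataset <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- generate_scenario(small_design(),
                                                  floor_model())
    memo
  }
})

# full laboratory-design dataset; generated once, reused across tests
lab_dataset <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- generate_scenario(preset_designs("lab_table1", seed = 101),
                                 floor_model())
    memo
  }
})

# three correlated Gaussian views of two classes, for learner tests
make_cluster_views <- function(n_per_class = 30, sep = 2, sd = 1,
                               d = 2, seed = 1) {
  set.seed(seed)
  base <- rbind(matrix(rnorm(n_per_class * d, -sep / 2, sd), n_per_class),
                matrix(rnorm(n_per_class * d, sep / 2, sd), n_per_class))
  views <- lapply(1:3, function(v) base + matrix(rnorm(length(base),
                                                       sd = 0.3 * sd),
                                                 nrow(base)))
  list(views = views, y = rep(c(-1, 1), each = n_per_class))
}

random_record <- function(n = 50, s = 3, fs = 100, label = "unlabeled") {
  accel_record(matrix(rnorm(n * s), n, s), fs = fs, label = label)
}
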