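# Worked-example per-channel rating cells from a published objective
# evaluation of passive and active female/male head-neck model
# configurations against low-speed rear-impact volunteer kinematics.
# They exercise the three aggregation schemes end to end and pin down
# the group/total arithmetic to three printed decimals.

#' Worked-example per-channel rating tables
#'
#' Four per-channel score tables from a published evaluation of head-neck
#' model configurations (passive baseline "PSV" plus combinations of
#' co-contraction CCo, parallel damping element PDE and the reflex
#' controller APF), used as worked examples for [aggregate_scores()]:
#'
#' \describe{
#'   \item{head_neck_active}{Ten displacement rating channels; columns:
#'     passive and fully active (PSV+PDE+CCo+APF) female and male
#'     head-neck models at 5.8 km/h.}
#'   \item{head_neck_configs}{The same ten channels for all eight female
#'     model configurations.}
#'   \item{injury_input}{Injury-criteria input channels (head x-acceleration
#'     at 5.8/8.1/10.0 km/h, C1-C7 rotational velocities at 5.8 km/h) for
#'     the four female configurations retaining PDE.}
#'   \item{full_body}{Full-body channels (head and T1 x-acceleration,
#'     C1-C7 rotational velocities) for female and male PSV+PDE+APF and
#'     PSV+CCo+PDE+APF configurations.}
#' }
#'
#' @return A named list of data frames; row names are channel names in
#'   the convention [aggregate_scores()] expects.
#' @export
example_rating_tables <- function() {
  hn_rows <- rating_channel_names()
  head_neck_active <- data.frame(
    female_passive = c(0.832, 0.523, 0.816, 0.944, 0.972, 0.938, 0.903,
                       0.877, 0.779, 0.705),
    female_active  = c(0.943, 0.644, 0.961, 0.880, 0.994, 0.942, 0.883,
                       0.895, 0.913, 0.707),
    male_passive   = c(0.761, 0.836, 0.757, 0.863, 0.827, 0.873, 0.905,
                       0.844, 0.670, 0.677),
    male_active    = c(0.864, 0.803, 0.813, 0.696, 0.833, 0.955, 0.857,
                       0.872, 0.802, 0.729),
    row.names = hn_rows)
  head_neck_configs <- data.frame(
    PSV                     = c(0.832, 0.523, 0.816, 0.944, 0.972, 0.938,
                                0.903, 0.877, 0.779, 0.705),
    `PSV+CCo`               = c(0.793, 0.431, 0.731, 0.792, 0.849, 0.877,
                                0.916, 0.902, 0.799, 0.687),
    `PSV+PDE`               = c(0.961, 0.810, 0.991, 0.952, 0.937, 0.874,
                                0.853, 0.905, 0.911, 0.692),
    `PSV+APF`               = c(0.868, 0.511, 0.820, 0.925, 0.979, 0.935,
                                0.863, 0.820, 0.781, 0.747),
    `PSV+CCo+PDE`           = c(0.880, 0.579, 0.930, 0.902, 0.987, 0.981,
                                0.940, 0.965, 0.855, 0.694),
    `PSV+CCo+APF`           = c(0.829, 0.428, 0.733, 0.781, 0.861, 0.912,
                                0.902, 0.832, 0.825, 0.752),
    `PSV+PDE+APF`           = c(0.994, 0.805, 0.989, 0.970, 0.919, 0.853,
                                0.818, 0.848, 0.966, 0.703),
    `PSV+CCo+PDE+APF`       = c(0.943, 0.644, 0.961, 0.880, 0.994, 0.942,
                                0.883, 0.895, 0.913, 0.707),
    row.names = hn_rows, check.names = FALSE)
  ii_rows <- c("HCG-ax@5.8", paste0("C", 1:7, "-ryv@5.8"),
               "HCG-ax@8.1", "HCG-ax@10.0")
  injury_input <- data.frame(
    `PSV+PDE`         = c(0.700, 0.660, 0.719, 0.804, 0.800, 0.822, 0.637,
                          0.383, 0.603, 0.625),
    `PSV+CCo+PDE`     = c(0.703, 0.713, 0.788, 0.907, 0.867, 0.780, 0.562,
                          0.381, 0.603, 0.625),
    `PSV+PDE+APF`     = c(0.717, 0.648, 0.691, 0.757, 0.713, 0.721, 0.654,
                          0.398, 0.620, 0.696),
    `PSV+CCo+PDE+APF` = c(0.726, 0.671, 0.770, 0.852, 0.765, 0.708, 0.600,
                          0.392, 0.606, 0.647),
    row.names = ii_rows, check.names = FALSE)
  fb_rows <- c("HCG-ax", paste0("C", 1:7, "-ryv"), "T1-ax")
  full_body <- data.frame(
    `female PSV+PDE+APF`     = c(0.751, 0.769, 0.632, 0.764, 0.730, 0.689,
                                 0.675, 0.456, 0.519),
    `female PSV+CCo+PDE+APF` = c(0.662, 0.764, 0.631, 0.736, 0.685, 0.610,
                                 0.684, 0.477, 0.498),
    `male PSV+PDE+APF`       = c(0.727, 0.794, 0.772, 0.661, 0.670, 0.743,
                                 0.750, 0.644, 0.567),
    `male PSV+CCo+PDE+APF`   = c(0.763, 0.784, 0.805, 0.695, 0.670, 0.726,
                                 0.807, 0.671, 0.557),
    row.names = fb_rows, check.names = FALSE)
  list(head_neck_active = head_neck_active,
       head_neck_configs = head_neck_configs,
       injury_input = injury_input,
       full_body = full_body)
}

#' Reference optimized controller/damping parameter sets
#'
#' Published optimum parameter values for the fully active female and
#' male head-neck models (proportional gain KPA in %contraction/rad,
#' derivative gain KDA in %contraction/(rad/ms), neural delay TNDA in ms,
#' parallel damping coefficient PDE in kN*ms/mm^2). Used as fixture truth
#' values in self-consistency experiments; note the male KPA sits on the
#' lower search bound.
#'
#' @return A data frame with rows `female` and `male`.
#' @export
reference_optimized_params <- function() {
  data.frame(kpa = c(0.1952, 0.01), kda = c(34.093, 93.48),
             tnda = c(4.233, 19.66), pde = c(0.0303, 0.0192),
             row.names = c("female", "male"))
}
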