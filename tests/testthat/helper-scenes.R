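# Shared fixture builders. All scenes are generated in code at test time;
# "binned scale" means 0.432 um/px, 3.5 s frames (the analysis scale).

# A constant-velocity single-mover scene with no stationary spots.
single_mover_scene <- function(v_umps = 0.35, n_frames = 30L, size = c(48L, 140L),
                               seed = 6L, angle = 0, ...) {
  sch <- list(list(list(start_frame = 1L, end_frame = n_frames,
                        vx_umps = v_umps * cos(angle),
                        vy_umps = v_umps * sin(angle))))
  make_scene_movie(scene_config(image_size = size, n_frames = n_frames,
                                n_stationary = 0L, n_moving = 1L,
                                mover_speeds = v_umps, run_pause_schedule = sch,
                                seed = seed, ...))
}

# A small mixed scene (stationary spots + movers) at the binned scale.
mixed_scene <- function(n_stationary = 80L, n_moving = 2L, n_frames = 40L,
                        size = c(144L, 144L), seed = 9L, ...) {
  make_scene_movie(scene_config(image_size = size, n_frames = n_frames,
                                n_stationary = n_stationary, n_moving = n_moving,
                                seed = seed, ...))
}

# Screen-well generator used by the synthetic-screen tests: fixed stationary
# population, configurable mover count (treatment halves it).
screen_well <- function(n_moving, seed, n_frames = 50L) {
  make_scene_movie(scene_config(
    image_size = c(192L, 192L), n_frames = n_frames, n_stationary = 110L,
    n_moving = n_moving, mover_speeds = rep(c(0.45, 0.55, 0.4, 0.5),
                                            length.out = max(n_moving, 1L)),
    seed = seed))
}

screen_cfg <- function() screen_config(bin_factor = 1L, register = FALSE)

# Reference calibration used throughout: 0.108 um/px camera binned 4x,
# 3.5 s frames stretched 2x.
ref_cal <- function() calibration(0.108, 3.5, bin_factor = 4, time_stretch = 2)

make_flat_movie <- function(value = 100, dims = c(16, 16, 5), cal = ref_cal()) {
  movie(array(value, dims), cal)
}
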