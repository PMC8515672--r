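# jawtrack

Reconstruction and analysis of three-dimensional mandibular movement
relative to the maxilla during mastication in small animals (mice), from
marker-based motion capture and micro-CT derived surface anatomy.

## The problem

The mandible is a rigid body moving with six degrees of freedom. Tracking a
single point on it cannot recover jaw kinematics; tracking **four markers**
rigidly attached to the mandible can. Given

* per-frame 3D positions of the markers from a stereo capture system
  (200 frames/s),
* surface meshes of mandible and maxilla segmented from micro-CT, with the
  marker positions and anatomical landmarks (incisor edge, molar mesiobuccal
  cusp, condylar points) recorded in the same CT frame, and
* a single static acquisition taken with the jaw fixed in the intercuspal
  position (teeth fully interdigitated), which rigidly couples the maxilla
  to the marker set,

`jawtrack` reconstructs the motion of **any** mandibular point relative to
the maxilla, the dynamic clearance between upper and lower dentition
("dynamic occlusion"), the segmentation of each chewing cycle into opening,
closing and occlusal phases, and the timing of masticatory-muscle EMG bursts
relative to those phases. A synthetic-data generator stands in for the
capture hardware, the micro-CT and the EMG amplifier, so the entire pipeline
is testable on a desk.

## The core computation

For each frame, the marker reference configuration \(a_i\) (CT frame) and the
observed markers \(b_i\) (capture frame) are registered by the least-squares
rigid transform (orthogonal Procrustes / Kabsch):

minimize over R ∈ SO(3), t ∈ R³:  Σᵢ ‖R aᵢ + t − bᵢ‖²

solved by aligning centroids and taking the SVD of the cross-covariance
H = Σᵢ ãᵢ b̃ᵢᵀ, with the determinant sign corrected so that only proper
rotations (no reflections) are returned. The same fit applied to the static
intercuspal acquisition places the maxilla in capture coordinates; composing
the per-frame mandible pose with the inverse static pose expresses all
motion in a maxilla-fixed anatomical frame (+X anterior, +Y animal-left,
+Z superior). Landmark trajectories, mesh clearance (exact vertex-to-surface
distance with a uniform-grid spatial index), phase segmentation and EMG
burst detection are all built on this.

## Worked example

```r
library(jawtrack)

spec       <- motion_spec(n_cycles = 3, seed = 1)   # chewing at 200 frames/s
truth      <- simulate_jaw_motion(spec)
capture    <- synth_capture(truth, noise_sigma_mm = 0, seed = 1)
dentition  <- synth_dentition(resolution_mm = 0.1)
model      <- anatomical_model(dentition$mandible, dentition$maxilla,
                               default_marker_geometry(), dentition$landmarks)

poses <- estimate_pose_series(capture, model$marker_reference)
poses
#> Pose series: 90 frames at 200 Hz, 0 invalid, mean fit RMSD 1.94e-15 mm

maxilla_pose <- register_maxilla_static(attr(capture, "static_frame"), model)
molar        <- landmark_trajectory(poses, maxilla_pose, model, "molar_cusp")
occlusion    <- contact_series(poses, maxilla_pose, model)
occlusion
#> Occlusion series: 90 frames, 15 in contact (threshold 0.05 mm), min clearance 2.22e-16 mm

segmentation <- detect_key_timepoints(molar, occlusion)
segmentation
#> Phase segmentation (molar_cusp): 3 complete cycle(s)
#>  cycle max_closing most_anterior max_opening most_posterior contact_onset consistent
#>      1           1            10          19             28            28       TRUE
#>      2          31            40          49             58            58       TRUE
#>      3          61            70          79             88            88       TRUE

phase_statistics(segmentation)$summary
#>         phase   mean_ms    sd_ms
#> 1  opening_ms  90.00000 0.000000
#> 2  closing_ms  45.00000 0.000000
#> 3 occlusal_ms  13.33333 2.886751
#> 4    cycle_ms 148.33333 2.886751
```

Reading the output: each 150-ms cycle (30 frames, 5 ms apart) starts at
maximum jaw closing, passes its most anterior point around frame 10,
reaches maximum opening at frame 19 and its most posterior point at frame
28 — which coincides with the onset of molar contact, the start of the
occlusal phase. The mean fit RMSD of 2e-15 mm confirms the noiseless
round trip is exact; with capture noise it reports the per-frame
registration quality instead.

`synth_emg()` adds phase-locked EMG (digastric active during opening;
working-side masseter onset in late closing, balancing-side masseter onset
at contact onset), and `preprocess_emg()` / `detect_bursts()` /
`align_to_frames()` recover those windows and map them onto capture frames.
`accuracy_grid()` and `resolution_test()` reproduce the system-evaluation
protocols (a 343-point calibration grid over a 3 mm cube in 0.5-mm steps,
and a dwell-step-dwell displacement-resolution test).

## Command line

An installed script exposes the pipeline as subcommands
(`simulate`, `track`, `register`, `trajectory`, `occlusion`, `phases`,
`emg`, `calibrate`, `run`):

```sh
JT=$(Rscript -e 'cat(system.file("exec", "jawtrack", package = "jawtrack"))')
Rscript $JT simulate --out demo --cycles 3
Rscript $JT run --config demo/config.yaml      # or assemble a config by hand
```

`run` executes pose estimation, static registration, trajectories,
occlusion, phase segmentation and EMG analysis in order and writes
CSV/JSON reports plus figures into the configured output directory;
identical configurations produce byte-identical reports.

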