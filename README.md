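# poselink

Multi-animal pose assembly, tracking and tracklet stitching in R.

Experiments that film several interacting animals — mice in an open field,
marmoset pairs, schooling fish — need more than keypoint detection: the
detected body parts must be grouped into the right individuals in every
frame, and those individuals must keep their identities through contacts,
crossings and occlusions. `poselink` implements the combinatorial half of a
bottom-up multi-animal pose pipeline, the part that sits between a trained
keypoint detector and the behavioural analysis:

- **Decoding** — score maps, location refinement fields and part affinity
  fields (PAFs) become subpixel keypoint proposals
  (`x* = p*λ + λ/2 + L_x(p*, q*)`) and pairwise limb affinity costs (the
  PAF line integral along the segment joining two proposals, normalized by
  its length).
- **Data-driven skeleton selection** — edges of the complete bodypart graph
  are ranked by the auROC separating within- from between-animal affinity
  cost distributions (bin width 0.01); the maximum spanning tree and its
  progressively redundant extensions are scored by assembly purity and
  connected-keypoint fraction, and the jointly best graph is retained.
- **Assembly** — per-edge optimal pairing, connected components, greedy
  linking with a bodypart conflict rule, an optional Mahalanobis gate
  against a Gaussian pose prior over pairwise keypoint distances, and an
  optional temporal coherence weight `(1/j) Σ exp(−γ Δt ‖c − c_n‖²)`.
- **Local tracking** — SORT-style Kalman trackers with Hungarian
  association: a bounding-box tracker (state `[x, y, A, r]` + velocities,
  IoU similarity) and a 2σ covariance error-ellipse tracker (state
  `[x, y, h, w, θ]` + velocities, similarity
  `c = 0.8(1−d) + 0.2(1−d)cos(θ_d − θ_p)`).
- **Tracklet stitching** — a min-cost network flow over a tracklet DAG
  (each tracklet split into unit-demand/unit-supply halves; `k` units of
  flow for `k` animals) with motion, spatial-proximity, shape (Hausdorff)
  and dynamic-similarity (Hankel rank ratio) affinities, optional
  appearance down-weighting from embedding cosine similarity, and greedy
  reinsertion of short residual tracklets.
- **Evaluation** — RMSE, PCK, OKS-mAP, assembly purity and unconnected
  fraction, CLEAR-MOT (MOTA, misses, false positives, switches, fragments,
  mostly-tracked), swap flagging and the Proximity Index.
- **Synthetic scenes** — a deterministic generator of multi-animal
  trajectories with occlusions, crossings and detection noise, which also
  renders the training-target tensors (binary score maps, subpixel offset
  fields, PAF unit-vector bands), so the entire pipeline runs and is tested
  without any external data.

## A worked example

Simulate three animals for 200 frames, corrupt the ground truth into noisy
detections, and run assembly → ellipse tracking → stitching → evaluation:

```r
library(poselink)

cfg   <- scene_config(n_animals = 3, n_frames = 200, seed = 11)
scene <- generate_scene(cfg)
scene
#> gt_scene: 200 frames, 3 animals, 5 bodyparts, 192x192 px (stride 4)

res <- run_pipeline(scene, pipeline_config(seed = 11))
res$mot            # stitched tracks vs ground truth
#> MOTA 0.952 | misses 21, FP 0, switches 3, fragments 10, MT 3 (of 504 gt)
res$mot_tracklets  # naive local-tracking baseline
#> MOTA 0.940 | misses 0, FP 3, switches 27, fragments 0, MT 3 (of 504 gt)
length(res$tracklets); length(res$tracks)
#> [1] 29
#> [1] 3
head(res$track_table)
#>   track_id frame bodypart        x        y confidence
#> 1        1     1        1 29.06176 172.0218  0.7987394
#> 2        1     1        3 25.82597 156.7015  0.7987394
#> 3        1     1        2 33.79448 165.0071  0.7987394
```

Local tracking alone propagates identities correctly while animals are
apart but accumulates 27 identity switches at crossings and occlusions;
stitching the 29 tracklets into 3 globally optimal tracks cuts that to 3
switches while keeping MOTA above 0.95. The `track_table` is the flat
per-keypoint output (one row per track, frame and bodypart) that analysis
code consumes; `write_tracks()` serializes it.

A thin command-line front-end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/poselink", package = "poselink"))')" \
    run --n-animals 3 --n-frames 200 --seed 11 --out out/
```

## Package layout

| Area | Functions |
| --- | --- |
| Simulation | `scene_config()`, `generate_scene()`, `render_targets()`, `corrupt_detections()`, `sample_crop_centers()` |
| Decoding | `smooth_scoremaps()`, `find_peaks()`, `refine_locations()`, `decode_detections()`, `paf_line_cost()`, `build_affinity_tables()` |
| Skeleton selection | `edge_cost_distributions()`, `rank_edges_auroc()`, `maximum_spanning_tree()`, `candidate_graphs()`, `select_graph()`, `prune_random_subgraph()` |
| Assembly | `pick_optimal_pairs()`, `connected_components()`, `greedy_link()`, `fit_pose_prior()`, `mahalanobis_gate()`, `temporal_coherence_weight()`, `assemble_frame()`, `assemble_video()` |
| Tracking | `bbox_from_keypoints()`, `iou()`, `fit_ellipse()`, `ellipse_similarity()`, `kalman_create()`, `kalman_step()`, `associate()`, `track_video()` |
| Stitching | `split_residuals()`, `compute_max_gap()`, `motion_affinity()`, `spatial_proximity()`, `shape_similarity()`, `dynamic_similarity()`, `combine_costs()`, `build_stitch_graph()`, `solve_flow()`, `stitch_tracklets()`, `reinsert_residuals()` |
| Identity | `soft_vote()`, `tracklet_cosine()`, `triplet_accuracy()` |
| Metrics | `rmse()`, `pck()`, `oks_map()`, `assembly_quality()`, `mot_evaluate()`, `flag_swaps()`, `proximity_index()` |
| I/O & pipeline | `read/write_detections()`, `read/write_tracks()`, `read/write_coco_json()`, `read/write_graph()`, `read/write_embeddings()`, `read/write_config()`, `pipeline_config()`, `run_pipeline()` |

The methods vignette (`vignettes/poselink-methods.Rmd`) documents the
models, the default parameters and the design decisions in detail.
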