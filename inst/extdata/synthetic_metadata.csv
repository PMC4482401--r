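"cell_id","species","cell_type","region","M","n_branches","total_length"
"syn-001","mouse","interneuron","hippocampus",330657,55,4396.6
"syn-002","mouse","ganglion","frontal lobe",426371,64,3946
"syn-003","mouse","ganglion","hippocampus",637857,61,5423
"syn-004","mouse","ganglion","retina",556757,66,3781
"syn-005","mouse","interneuron","hippocampus",689258,55,2510.2
"syn-006","mouse","ganglion","retina",740974,64,4686.6
"syn-007","mouse","interneuron","frontal lobe",465659,58,4523.6
"syn-008","mouse","interneuron","hippocampus",339728,70,3279.2
"syn-009","mouse","ganglion","frontal lobe",389483,57,5190.7
"syn-010","mouse","interneuron","retina",306977,64,5693.8
"syn-011","mouse","ganglion","frontal lobe",275281,59,4228.5
"syn-012","mouse","ganglion","frontal lobe",678056,50,3346.7
"syn-013","rat","interneuron","frontal lobe",502877,59,5294.2
"syn-014","rat","ganglion","retina",600193,57,3112.6
"syn-015","rat","interneuron","frontal lobe",741641,67,1823.8
"syn-016","rat","ganglion","retina",736753,66,5264.8
"syn-017","rat","ganglion","hippocampus",507554,60,2358.8
"syn-018","rat","interneuron","frontal lobe",536839,56,3376.8
"syn-019","rat","interneuron","retina",649090,64,4045.3
"syn-020","rat","ganglion","hippocampus",953538,54,1728.3
"syn-021","rat","pyramidal","hippocampus",1144322,53,4119.3
"syn-022","rat","ganglion","frontal lobe",898606,74,2283.5
"syn-023","rat","interneuron","retina",343826,57,4583.5
"syn-024","rat","interneuron","frontal lobe",728613,67,2753.5
"syn-025","human","ganglion","frontal lobe",349005,62,3621.5
"syn-026","human","interneuron","hippocampus",371794,47,3641.8
"syn-027","human","interneuron","frontal lobe",395529,64,2341.6
"syn-028","human","ganglion","frontal lobe",302181,59,3057
"syn-029","human","pyramidal","hippocampus",257050,64,4589.2
"syn-030","human","ganglion","frontal lobe",370647,55,4757.9
"syn-031","human","interneuron","retina",229081,63,4349.7
"syn-032","human","pyramidal","hippocampus",356402,60,1721.7
"syn-033","human","ganglion","hippocampus",330113,48,2112.5
"syn-034","human","pyramidal","frontal lobe",322744,58,4019.3
"syn-035","human","pyramidal","frontal lobe",249594,53,3124.7
"syn-036","human","pyramidal","hippocampus",621594,66,4422
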