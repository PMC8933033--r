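17:34:36 hrtcst 0.1.0 starting, seed 1
17:34:36 stage profiles_io failed: abundance and metadata paths are required
17:34:36 hrtcst 0.1.0 starting, seed 1
17:34:36 stage profiles_io failed: abundance and metadata paths are required
17:35:11 hrtcst 0.1.0 starting, seed 1
17:35:11 stage profiles_io failed: abundance and metadata paths are required
17:35:12 hrtcst 0.1.0 starting, seed 1
17:35:12 stage profiles_io failed: abundance and metadata paths are required
17:36:12 hrtcst 0.1.0 starting, seed 1
17:36:12 stage profiles_io failed: abundance and metadata paths are required
17:36:13 hrtcst 0.1.0 starting, seed 1
17:36:13 stage profiles_io failed: abundance and metadata paths are required
17:38:05 hrtcst 0.1.0 starting, seed 1
17:38:05 stage profiles_io failed: abundance and metadata paths are required
17:38:05 hrtcst 0.1.0 starting, seed 1
17:38:05 stage profiles_io failed: abundance and metadata paths are required
17:38:59 hrtcst 0.1.0 starting, seed 1
17:38:59 stage profiles_io failed: abundance and metadata paths are required
17:38:59 hrtcst 0.1.0 starting, seed 1
17:38:59 stage profiles_io failed: abundance and metadata paths are required
17:39:28 hrtcst 0.1.0 starting, seed 1
17:39:28 stage profiles_io failed: abundance and metadata paths are required
17:39:28 hrtcst 0.1.0 starting, seed 1
17:39:28 stage profiles_io failed: abundance and metadata paths are required
17:40:04 hrtcst 0.1.0 starting, seed 1
17:40:04 stage profiles_io failed: abundance and metadata paths are required
17:40:05 hrtcst 0.1.0 starting, seed 1
17:40:05 stage profiles_io failed: abundance and metadata paths are required
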