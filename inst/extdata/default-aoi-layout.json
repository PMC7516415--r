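{
  "frame": {"width": 1920, "height": 1080},
  "priority": ["PA", "CA", "TW", "LW", "RW"],
  "regions": {
    "TW": [[120, 140], [1800, 140], [1800, 320], [120, 320]],
    "LW": [[120, 320], [440, 320], [440, 780], [120, 780]],
    "CA": [[440, 320], [1480, 320], [1480, 780], [440, 780]],
    "RW": [[1480, 320], [1800, 320], [1800, 780], [1480, 780]],
    "PA": [[120, 780], [1800, 780], [1800, 1000], [120, 1000]]
  }
}
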