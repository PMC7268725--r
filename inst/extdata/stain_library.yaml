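# Stain combination library for colour-deconvolution edge enhancement.
# Each entry: a name, the optical-density absorption vector for the three
# (L, a, b) channels, and the mean (L, a, b) centroid of the image group the
# combination serves best (used for automatic selection). The all-zero
# "white" vector denotes a pure-brightness absorber and is completed to
# (1, 1, 1)/sqrt(3) when the OD matrix is built.
#
# The shipped centroids are synthetic: they are the fruit-region Lab means
# of the package's three generated colourways (yellow, pale, red). For real
# photographs, replace them with centroids measured on your own training
# images.
- name: "methyl green"
  vector: [0.98003, 0.144316, 0.133146]
  lab_centroid: [140.6, 125.8, 146.8]
- name: "hematoxylin GL"
  vector: [0.644211, 0.716556, 0.266844]
  lab_centroid: [85.6, 143.4, 149.1]
- name: "white"
  vector: [0.0, 0.0, 0.0]
  lab_centroid: [140.2, 124.5, 169.2]
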