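"Image","Object ID","Centroid X um","Centroid Y um","Class","Cell: Area um^2"
"synthetic_section.ome.tif","cell-0001",120.78,59.98,"CD133: Negative",72.4
"synthetic_section.ome.tif","cell-0002",331.09,174.11,"CD133: Negative",56
"synthetic_section.ome.tif","cell-0003",171.77,173.76,"CD133: Negative",55.4
"synthetic_section.ome.tif","cell-0004",370.87,154.92,"CD133: Negative",51
"synthetic_section.ome.tif","cell-0005",395,64.03,"CD133: Positive",58.5
"synthetic_section.ome.tif","cell-0006",19.13,58.3,"CD133: Negative",89.2
"synthetic_section.ome.tif","cell-0007",221.8,97.87,"CD133: Negative",47.7
"synthetic_section.ome.tif","cell-0008",374.82,195.7,"CD133: Negative",44.6
"synthetic_section.ome.tif","cell-0009",231.6,111.71,"CD133: Negative",47.1
"synthetic_section.ome.tif","cell-0010",191.78,360.29,"CD133: Negative",74.5
"synthetic_section.ome.tif","cell-0011",401.87,19.25,"CD133: Positive",71
"synthetic_section.ome.tif","cell-0012",190.4,185.72,"CD133: Negative",84.6
"synthetic_section.ome.tif","cell-0013",284.58,335.55,"CD133: Negative",73.6
"synthetic_section.ome.tif","cell-0014",240.51,51.2,"CD133: Negative",76.9
"synthetic_section.ome.tif","cell-0015",43.23,235.6,"CD133: Negative",66.1
"synthetic_section.ome.tif","cell-0016",377.93,86.74,"CD133: Negative",73
"synthetic_section.ome.tif","cell-0017",103.36,53.56,"CD133: Negative",81.1
"synthetic_section.ome.tif","cell-0018",17.67,316.39,"CD133: Positive",79.3
"synthetic_section.ome.tif","cell-0019",137.73,375.92,"CD133: Negative",89
"synthetic_section.ome.tif","cell-0020",400.89,157.27,"CD133: Negative",62
"synthetic_section.ome.tif","cell-0021",373.61,279.35,"CD133: Negative",55.6
"synthetic_section.ome.tif","cell-0022",290.98,39.83,"CD133: Negative",60.5
"synthetic_section.ome.tif","cell-0023",269.01,161.27,"CD133: Negative",40.5
"synthetic_section.ome.tif","cell-0024",417.59,115.24,"CD133: Negative",49.2
"synthetic_section.ome.tif","cell-0025",275.4,342.15,"CD133: Negative",82.1
"synthetic_section.ome.tif","cell-0026",297.58,188.38,"CD133: Negative",51.6
"synthetic_section.ome.tif","cell-0027",228.51,340.23,"CD133: Negative",52
"synthetic_section.ome.tif","cell-0028",249.54,341.2,"CD133: Negative",43.8
"synthetic_section.ome.tif","cell-0029",121.45,333.62,"CD133: Negative",52.3
"synthetic_section.ome.tif","cell-0030",61.79,184.73,"CD133: Positive",76.6
"synthetic_section.ome.tif","cell-0031",404.47,316.88,"CD133: Negative",82.4
"synthetic_section.ome.tif","cell-0032",378.97,264.27,"CD133: Negative",64.9
"synthetic_section.ome.tif","cell-0033",290.1,298.28,"CD133: Positive",59.4
"synthetic_section.ome.tif","cell-0034",334.1,0.26,"CD133: Negative",52.3
"synthetic_section.ome.tif","cell-0035",10.34,199.63,"CD133: Negative",45.6
"synthetic_section.ome.tif","cell-0036",200.67,92.45,"CD133: Positive",59.5
"synthetic_section.ome.tif","cell-0037",318.55,159.52,"CD133: Negative",68.6
"synthetic_section.ome.tif","cell-0038",90.89,257.36,"CD133: Negative",50.8
"synthetic_section.ome.tif","cell-0039",133.64,147.76,"CD133: Negative",62.2
"synthetic_section.ome.tif","cell-0040",97.28,46.68,"CD133: Negative",50.9
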