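"texture_class","sand","silt","clay"
"sand",91.661,5.008,3.331
"loamy sand",81.662,12.505,5.833
"sandy loam",64.597,24.991,10.412
"loam",41.069,40.586,18.345
"silt loam",21.477,65.309,13.214
"silt",7.434,87.422,5.144
"sandy clay loam",59.825,13.075,27.1
"clay loam",32.5,34,33.5
"silty clay loam",10,56.5,33.5
"sandy clay",51.663,6.674,41.663
"silty clay",6.666,46.668,46.666
"clay",19.522,17.557,62.921
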