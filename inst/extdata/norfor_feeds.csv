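type,code,quality,dm,ash,crude_protein,crude_fat,ndf,total_acids,sugar,starch,nel
silage,1,very_high,332,77,167,39,436,62,92,,7.0
silage,2,medium,325,70,157,35,511,63,53,,6.1
silage,3,low,320,68,150,34,538,64,43,,5.7
concentrate,I,high,879,83,200,59,182,,,301,8.0
concentrate,II,medium,873,76,194,52,208,,,307,7.7
concentrate,III,low,873,76,182,46,202,,,390,7.5
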