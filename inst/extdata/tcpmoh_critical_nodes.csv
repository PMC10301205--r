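group,dpf,kind,nodes
0.5uM,2,degree,-
0.5uM,3,degree,"PE,YSE"
0.5uM,4,degree,"PE,YSE"
0.5uM,5,degree,"PE,YSE"
0.5uM,6,degree,SD
0.5uM,7,degree,SD
1uM,2,degree,-
1uM,3,degree,-
1uM,4,degree,-
1uM,5,degree,YSE
1uM,6,degree,YSE
1uM,7,degree,YSE
5uM,2,degree,"PE,CM"
5uM,3,degree,PE
5uM,4,degree,YSE
5uM,5,degree,PE
5uM,6,degree,PE
5uM,7,degree,YSE
0.5uM,2,eigen,-
0.5uM,3,eigen,"PE,YSE"
0.5uM,4,eigen,"PE,YSE"
0.5uM,5,eigen,"PE,YSE"
0.5uM,6,eigen,SD
0.5uM,7,eigen,SD
1uM,2,eigen,-
1uM,3,eigen,-
1uM,4,eigen,-
1uM,5,eigen,YSE
1uM,6,eigen,YSE
1uM,7,eigen,YSE
5uM,2,eigen,"PE,CM"
5uM,3,eigen,PE
5uM,4,eigen,YSE
5uM,5,eigen,PE
5uM,6,eigen,PE
5uM,7,eigen,PE
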