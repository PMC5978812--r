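cell_id,vertex_order,x,y
1,1,0.0,0.0
1,2,1.1,0.0
1,3,1.5,0.9
1,4,0.8,1.6
1,5,-0.3,1.0
2,1,1.1,0.0
2,2,2.4,0.1
2,3,2.9,1.1
2,4,2.2,1.8
2,5,1.5,0.9
3,1,0.8,1.6
3,2,1.5,0.9
3,3,2.2,1.8
3,4,1.9,2.8
3,5,0.9,2.7
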