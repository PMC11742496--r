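sample_id,condition,fatty_acid,percent
control,control F/2 medium,C14:0,7.25
control,control F/2 medium,C16:0,24.94
control,control F/2 medium,C18:0,ND
control,control F/2 medium,C20:0,ND
control,control F/2 medium,C16:1t,26.77
control,control F/2 medium,C17:1,ND
control,control F/2 medium,C18:1t,1.80
control,control F/2 medium,C24:1,3.52
control,control F/2 medium,C18:1(n-9),ND
control,control F/2 medium,C18:2(n-6),2.68
control,control F/2 medium,C18:3(n-6),1.96
control,control F/2 medium,C20:5n3,7.04
control,control F/2 medium,C20:3n3,ND
control,control F/2 medium,C18:3n3,ND
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C14:0,6.27
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C16:0,39.84
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C18:0,1.22
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C20:0,1.39
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C16:1t,14.04
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C17:1,ND
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C18:1t,ND
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C24:1,ND
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C18:1(n-9),6.55
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C18:2(n-6),4.76
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C18:3(n-6),3.38
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C20:5n3,4.80
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C20:3n3,0.82
optimized,-50%N +50%P zero-Si 2 g/L glycerol low blue light,C18:3n3,0.93
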