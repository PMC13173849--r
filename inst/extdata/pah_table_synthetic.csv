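"id","iupac_name","xyz_file","n_carbon","n_hydrogen","bay","fjord","harbor","canyon","topology","carcinogenicity","log_p","log_iball"
"benzene","benzene","benzene.xyz",6,6,0,0,0,0,"linear","-",2.37,
"naphthalene","naphthalene","naphthalene.xyz",10,8,0,0,0,0,"linear","-",2.89,
"anthracene","anthracene","anthracene.xyz",14,10,0,0,0,0,"linear","-",,
"tetracene","tetracene","tetracene.xyz",18,12,0,0,0,0,"linear","-",4.93,
"pentacene","pentacene","pentacene.xyz",22,14,0,0,0,0,"linear","L",5.78,0.01
"phenanthrene","phenanthrene","phenanthrene.xyz",14,10,1,0,0,0,"angular","-",3.88,
"chrysene","chrysene","chrysene.xyz",18,12,2,0,0,0,"angular","L",5.1,0.02
"benzo[c]phenanthrene","benzo[c]phenanthrene","benzo_c_phenanthrene.xyz",18,12,0,1,0,0,"angular","M",4.78,0.52
"triphenylene","triphenylene","triphenylene.xyz",18,12,3,0,0,0,"angular","-",,
"pyrene","pyrene","pyrene.xyz",16,10,0,0,0,0,"peri-condensed","-",4.34,
"benzo[a]pyrene","benzo[a]pyrene","benzo_a_pyrene.xyz",20,12,1,0,0,0,"peri-condensed","H",5.51,0.95
"perylene","perylene","perylene.xyz",20,12,2,0,0,0,"peri-condensed","-",5.71,
"coronene","coronene","coronene.xyz",24,12,0,0,0,0,"peri-condensed","-",5.87,
"pentahelicene","pentahelicene","pentahelicene.xyz",22,14,0,0,1,0,"angular","LM",,2.43
"hexahelicene","hexahelicene","hexahelicene.xyz",26,16,0,0,0,1,"angular","M",6.57,1.08
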