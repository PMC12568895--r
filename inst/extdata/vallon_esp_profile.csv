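"congener","phase","fraction","units"
"2,3,7,8-TeCDD","gaseous",0.1,"percent"
"1,2,3,7,8-PeCDD","gaseous",0.4,"percent"
"1,2,3,4,7,8-HxCDD","gaseous",0.4,"percent"
"1,2,3,6,7,8-HxCDD","gaseous",0.8,"percent"
"1,2,3,7,8,9-HxCDD","gaseous",0.5,"percent"
"1,2,3,4,6,7,8-HpCDD","gaseous",3.8,"percent"
"OCDD","gaseous",11.1,"percent"
"2,3,7,8-TeCDF","gaseous",0.6,"percent"
"1,2,3,7,8-PeCDF","gaseous",0.9,"percent"
"2,3,4,7,8-PeCDF","gaseous",1.8,"percent"
"1,2,3,4,7,8-HxCDF","gaseous",1.3,"percent"
"1,2,3,6,7,8-HxCDF","gaseous",1.5,"percent"
"1,2,3,7,8,9-HxCDF","gaseous",0.1,"percent"
"2,3,4,6,7,8-HxCDF","gaseous",3.7,"percent"
"1,2,3,4,6,7,8-HpCDF","gaseous",8.3,"percent"
"1,2,3,4,7,8,9-HpCDF","gaseous",1.2,"percent"
"OCDF","gaseous",8.3,"percent"
"2,3,7,8-TeCDD","particulate",0.1,"percent"
"1,2,3,7,8-PeCDD","particulate",0.3,"percent"
"1,2,3,4,7,8-HxCDD","particulate",0.4,"percent"
"1,2,3,6,7,8-HxCDD","particulate",0.7,"percent"
"1,2,3,7,8,9-HxCDD","particulate",0.5,"percent"
"1,2,3,4,6,7,8-HpCDD","particulate",4.6,"percent"
"OCDD","particulate",14.9,"percent"
"2,3,7,8-TeCDF","particulate",0.4,"percent"
"1,2,3,7,8-PeCDF","particulate",0.8,"percent"
"2,3,4,7,8-PeCDF","particulate",1.7,"percent"
"1,2,3,4,7,8-HxCDF","particulate",1.4,"percent"
"1,2,3,6,7,8-HxCDF","particulate",2,"percent"
"1,2,3,7,8,9-HxCDF","particulate",0.2,"percent"
"2,3,4,6,7,8-HxCDF","particulate",3.8,"percent"
"1,2,3,4,6,7,8-HpCDF","particulate",9.4,"percent"
"1,2,3,4,7,8,9-HpCDF","particulate",1.6,"percent"
"OCDF","particulate",12.4,"percent"
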