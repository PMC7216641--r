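subclass_id,class,size_label,diameter_nm
XXL_VLDL_P,VLDL,extremely large VLDL,75
XL_VLDL_P,VLDL,very large VLDL,64
L_VLDL_P,VLDL,large VLDL,53.6
M_VLDL_P,VLDL,medium VLDL,44.5
S_VLDL_P,VLDL,small VLDL,36.8
XS_VLDL_P,VLDL,very small VLDL,31.3
IDL_P,IDL,IDL,28.6
L_LDL_P,LDL,large LDL,25.5
M_LDL_P,LDL,medium LDL,23
S_LDL_P,LDL,small LDL,18.7
XL_HDL_P,HDL,very large HDL,14.3
L_HDL_P,HDL,large HDL,12.1
M_HDL_P,HDL,medium HDL,10.9
S_HDL_P,HDL,small HDL,8.7
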