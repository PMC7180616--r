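<?xml version="1.0"?>
<annotation>
  <filename>synthetic_scene_0001</filename>
  <size>
    <width>256</width>
    <height>256</height>
    <depth>3</depth>
  </size>
  <object>
    <name>tomato</name>
    <bndbox>
      <xmin>0</xmin>
      <ymin>0</ymin>
      <xmax>4</xmax>
      <ymax>4</ymax>
    </bndbox>
  </object>
  <object>
    <name>tomato</name>
    <bndbox>
      <xmin>24</xmin>
      <ymin>100</ymin>
      <xmax>60</xmax>
      <ymax>140</ymax>
    </bndbox>
  </object>
</annotation>
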